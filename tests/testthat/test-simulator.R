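test_that("companion-matrix stability matches scalar and 2x2 hand cases", {
  expect_true(is_stable(array(0.9, c(1, 1, 1))))
  expect_false(is_stable(array(1.1, c(1, 1, 1))))
  # eigenvalues of [[.5,.5],[.5,.5]] are {1, 0}: unit root, not stable
  expect_false(is_stable(matrix(0.5, 2, 2)))
  expect_true(is_stable(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)))
  # univariate AR(2) boundary: a1 + a2 = 1 has a unit root
  expect_false(is_stable(array(c(0.5, 0.5), c(2, 1, 1))))
})

test_that("stability predicts boundedness of simulated trajectories", {
  set.seed(17)
  n_checked <- 0
  while (n_checked < 20) {
    p <- sample(1:3, 1); d <- sample(2:3, 1)
    A <- array(rnorm(p * d * d, sd = 0.45 / sqrt(p * d)), c(p, d, d))
    scale <- runif(1, 0.3, 2.2)
    A <- A * scale
    # companion radius, computed independently of is_stable
    comp <- matrix(0, d * p, d * p)
    for (k in seq_len(p)) comp[1:d, ((k - 1) * d + 1):(k * d)] <- A[k, , ]
    if (p > 1) comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
    rad <- max(Mod(eigen(comp, only.values = TRUE)$values))
    if (abs(rad - 1) < 0.05) next  # skip near-critical systems
    n_checked <- n_checked + 1
    x <- matrix(rnorm(p * d), p, d)  # rows: recent history
    bounded <- TRUE
    hist <- x
    for (t in 1:3000) {
      new <- rnorm(d, sd = 0.01)
      for (k in 1:p) new <- new + as.numeric(A[k, , ] %*% hist[k, ])
      hist <- rbind(new, hist)[1:p, , drop = FALSE]
      if (max(abs(new)) > 1e6) { bounded <- FALSE; break }
    }
    expect_identical(is_stable(A), bounded)
  }
})

test_that("surrogate networks satisfy their construction invariants", {
  for (seed in c(1, 7, 23, 50, 88)) {
    model <- surrogate_network(sim_config(), seed = seed)
    d <- 10
    expect_true(all(diag(model$structural_mask)))
    expect_true(all(model$structural_mask[model$dynamic_mask]))
    off <- !diag(d)
    # structural density within the configured range
    expect_gte(mean(model$structural_mask[off]), 0.6 - 0.05)
    expect_lte(mean(model$structural_mask[off]), 0.8 + 0.05)
    # interactions only on dynamic links, at half magnitude
    nz <- apply(model$coefficients != 0, c(3, 4), any)
    expect_true(all(nz[off] == model$dynamic_mask[off]))
    for (k in 1:6) {
      mk <- matrix(model$coefficients[, k, , ], 400)
      expect_lte(max(abs(mk[, as.vector(off)])), 0.25)
    }
    # diagonal AR(2) from the magnitude grid, fixed across regimes
    grid <- seq(0.1, 0.5, by = 0.01)
    for (j in 1:d) {
      expect_true(all(abs(model$coefficients[, 1, j, j] -
                          model$coefficients[1, 1, j, j]) < 1e-12))
      expect_lt(min(abs(model$coefficients[1, 1, j, j] - grid)), 1e-9)
      expect_lt(min(abs(model$coefficients[1, 2, j, j] - grid)), 1e-9)
      expect_true(all(model$coefficients[, 3:6, j, j] == 0))
    }
    # regimes: at least 150 ms long and individually stable
    lens <- diff(c(model$regime_bounds, 401L))
    expect_true(all(lens >= 30))
    for (r in model$regime_bounds)
      expect_true(is_stable(model$coefficients[r, , , ]))
  }
})

test_that("two-node forced configuration enumerates its masks", {
  cfg <- sim_config(d = 2, density_range = c(1, 1), dynamic_fraction = 1)
  model <- surrogate_network(cfg, seed = 4)
  expect_true(all(model$structural_mask))
  expect_equal(sum(model$dynamic_mask), 2L)  # both directed links dynamic
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m1 <- surrogate_network(sim_config(d = 4), seed = 99)
  m2 <- surrogate_network(sim_config(d = 4), seed = 99)
  expect_identical(m1$coefficients, m2$coefficients)
  y1 <- simulate_trials(m1, N = 12, seed = 5)
  y2 <- simulate_trials(m2, N = 12, seed = 5)
  expect_identical(y1$data, y2$data)
})

test_that("generative noise has unit variance and the target trial coupling", {
  # null dynamics: the output is the (correlated) generative noise itself
  null_model <- structure(
    list(coefficients = array(0, c(300, 1, 3, 3)), fs = 200),
    class = "network_model")
  means <- sds <- numeric(4)
  set.seed(2)
  for (i in 1:4) {
    y <- simulate_trials(null_model, N = 150, trial_corr = c(0.1, 0.07))
    expect_lt(abs(var(as.numeric(y$data)) - 1), 0.02)
    flat <- matrix(y$data, 150)  # trials x (channel, time)
    cm <- cor(t(flat))
    means[i] <- mean(cm[lower.tri(cm)])
    sds[i] <- sd(cm[lower.tri(cm)])
  }
  expect_gte(mean(means), 0.05)
  expect_lte(mean(means), 0.15)
  expect_lt(abs(mean(sds) - 0.07), 0.05)
})

test_that("self-dynamics reproduce the imposed lag-1 autocorrelation", {
  demo <- bivariate_demo(samples = 600, trials = 80, coupling = 0,
                         window = c(250, 350), seed = 31)
  acf1 <- mean(apply(demo$Y$data, c(1, 2), function(x)
    cor(x[-1], x[-length(x)])))
  expect_lt(abs(acf1 - 0.9), 0.02)
  # with zero coupling the channels stay uncorrelated
  cc <- mean(sapply(1:80, function(n)
    cor(demo$Y$data[n, 1, ], demo$Y$data[n, 2, ])))
  expect_lt(abs(cc), 0.1)
})

test_that("observation noise hits the requested power ratio", {
  set.seed(55)
  y <- array(rnorm(100 * 2 * 600, sd = 2), c(100, 2, 600))
  noisy <- add_observation_noise(y, snr = 1)
  ratio <- mean(y^2) / mean((noisy - y)^2)
  expect_gte(ratio, 0.95); expect_lte(ratio, 1.05)
  # snr -> infinity leaves the input untouched (relative 1e-4)
  clean <- add_observation_noise(y, snr = 1e12)
  expect_lt(max(abs(clean - y)) / max(abs(y)), 1e-4)
  # decibel flag converts before scaling
  set.seed(1); a <- add_observation_noise(y, snr = 10, units = "db")
  set.seed(1); b <- add_observation_noise(y, snr = 10^(10 / 10))
  expect_identical(a, b)
})

test_that("spatial mixing kernel follows the Gaussian point spread", {
  pos <- matrix(c(0, 20, 0, 0), 2, 2)  # two nodes 20 mm apart
  y <- array(rnorm(4 * 2 * 50), c(4, 2, 50))
  mixed <- apply_spatial_mixing(y, pos, sigma = 20)
  w <- exp(-0.5)  # exp(-400 / (2 * 400))
  expected <- (y[, 1, ] * 1 + y[, 2, ] * w) / (1 + w)
  expect_equal(mixed[, 1, ], expected, tolerance = 1e-12)
  # a vanishing kernel reduces to the identity
  almost_id <- apply_spatial_mixing(y, pos, sigma = 1e-6)
  expect_equal(almost_id, y, tolerance = 1e-12)
})

test_that("the two-node demo exposes the printed parameterization", {
  demo <- get_demo()
  A <- demo$model$coefficients
  expect_equal(dim(A), c(1000L, 1L, 2L, 2L))
  expect_true(all(A[, 1, 1, 1] == 0.9) && all(A[, 1, 2, 2] == 0.9))
  expect_true(all(A[, 1, 2, 1] == 0))
  expect_equal(as.integer(table(A[, 1, 1, 2])), c(800L, 200L))  # 200-sample window
  expect_true(all(A[401:600, 1, 1, 2] == 0.5))
  expect_equal(dim(demo$Y$data), c(200L, 2L, 1000L))
  expect_error(bivariate_demo(diag_coef = 1.05), "unstable")
})
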