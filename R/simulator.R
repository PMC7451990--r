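# Ground-truth generators: regime-switching surrogate networks driven by a
# reduced AR(6) process, the two-node coupling demo, and corruption operators
# (additive observation noise, Gaussian spatial mixing).

#' Surrogate-network simulation configuration
#'
#' Bundles the parameters of the regime-switching surrogate networks.
#' Diagonal (self) dynamics are AR(2) pairs with positive coefficients on
#' lags 1-2, producing dominant low-frequency oscillations; each directed
#' interaction is an AR(2)-style signed pair placed at consecutive lags with
#' a random onset delay of up to `max_delay` samples, so the true model order
#' is `max_delay + 1`.
#'
#' @param d Number of nodes.
#' @param n_trials Number of trials.
#' @param fs Sampling rate (Hz).
#' @param duration Recording length in seconds.
#' @param density_range Range of the structural link density over ordered
#'   node pairs; the density itself is drawn uniformly within it.
#' @param dynamic_fraction Fraction of structural links that carry directed
#'   interactions.
#' @param n_regimes Number of quasi-stationary connectivity regimes.
#' @param coef_range,coef_step Magnitude grid for AR coefficients (drawn from
#'   `seq(coef_range[1], coef_range[2], by = coef_step)`).
#' @param offdiag_scale Scaling of off-diagonal (interaction) magnitudes
#'   relative to the grid (interactions at half magnitude by default).
#' @param trial_corr Target mean and sd of the pairwise correlation of the
#'   generative noise across trials.
#' @param min_regime_sec Minimum regime duration in seconds.
#' @param max_delay Maximum interaction onset delay in samples.
#' @param max_iter Maximum stability redraws per regime.
#' @return A classed list of validated settings.
#' @export
sim_config <- function(d = 10L, n_trials = 200L, fs = 200, duration = 2,
                       density_range = c(0.6, 0.8), dynamic_fraction = 0.5,
                       n_regimes = 3L, coef_range = c(0.1, 0.5),
                       coef_step = 0.01, offdiag_scale = 0.5,
                       trial_corr = c(0.1, 0.07), min_regime_sec = 0.150,
                       max_delay = 5L, max_iter = 1000L) {
  stopifnot(d >= 2L, n_trials >= 1L, fs > 0, duration > 0,
            length(density_range) == 2L, all(density_range > 0),
            all(density_range <= 1), density_range[1] <= density_range[2],
            dynamic_fraction > 0, dynamic_fraction <= 1, n_regimes >= 1L,
            length(coef_range) == 2L, coef_range[1] > 0, coef_step > 0,
            offdiag_scale > 0, length(trial_corr) == 2L,
            min_regime_sec > 0, max_delay >= 1L)
  structure(list(d = as.integer(d), n_trials = as.integer(n_trials), fs = fs,
                 duration = duration, density_range = density_range,
                 dynamic_fraction = dynamic_fraction,
                 n_regimes = as.integer(n_regimes), coef_range = coef_range,
                 coef_step = coef_step, offdiag_scale = offdiag_scale,
                 trial_corr = trial_corr, min_regime_sec = min_regime_sec,
                 max_delay = as.integer(max_delay),
                 p_true = as.integer(max_delay) + 1L,
                 max_iter = as.integer(max_iter)),
            class = "sim_config")
}

#' Stability of an MVAR coefficient block
#'
#' Builds the `d*p x d*p` companion matrix of an order-`p` MVAR coefficient
#' block and tests whether its spectral radius is below 1 (all eigenvalue
#' moduli strictly less than one), the asymptotic-stability condition for a
#' discrete-time VAR.
#'
#' @param A Coefficient array `[p x d x d]` (a `[d x d]` matrix is treated as
#'   order 1).
#' @return `TRUE` if stable.
#' @export
is_stable <- function(A) {
  if (is.matrix(A)) A <- array(A, c(1L, dim(A)))
  dm <- dim(A)
  if (length(dm) != 3L || dm[2] != dm[3]) stop("`A` must be [p x d x d]")
  if (!all(is.finite(A))) stop("`A` must be finite")
  p <- dm[1]; d <- dm[2]
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[1:d, ((k - 1) * d + 1):(k * d)] <- A[k, , ]
  if (p > 1L) comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
}

# Draw the off-diagonal coefficient block for one regime.
draw_offdiag <- function(cfg, links) {
  d <- cfg$d; p <- cfg$p_true
  grid <- seq(cfg$coef_range[1], cfg$coef_range[2], by = cfg$coef_step)
  B <- array(0, c(p, d, d))
  for (i in seq_len(nrow(links))) {
    delta <- sample.int(cfg$max_delay, 1L)
    mag <- sample(grid, 2L, replace = TRUE) * cfg$offdiag_scale
    sgn <- sample(c(-1, 1), 2L, replace = TRUE)
    B[delta,     links[i, 1], links[i, 2]] <- sgn[1] * mag[1]
    B[delta + 1, links[i, 1], links[i, 2]] <- sgn[2] * mag[2]
  }
  B
}

new_network_model <- function(coefficients, structural_mask, dynamic_mask,
                              regime_bounds, fs, min_len) {
  d <- ncol(structural_mask)
  Tn <- dim(coefficients)[1]
  stopifnot(all(dynamic_mask[!structural_mask] == FALSE),
            all(diag(structural_mask)))
  nz <- apply(coefficients != 0, c(3, 4), any)
  offdiag <- !diag(d)
  if (any(nz[offdiag] & !dynamic_mask[offdiag]))
    stop("nonzero interaction outside the dynamic mask")
  lens <- diff(c(regime_bounds, Tn + 1L))
  if (any(lens < min_len)) stop("regime shorter than the minimum duration")
  for (r in seq_along(regime_bounds))
    if (!is_stable(coefficients[regime_bounds[r], , , ]))
      stop("unstable regime in constructed model")
  structure(list(coefficients = coefficients,
                 structural_mask = structural_mask,
                 dynamic_mask = dynamic_mask,
                 regime_bounds = regime_bounds, fs = fs,
                 order = dim(coefficients)[2]),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  dm <- dim(x$coefficients)
  cat(sprintf("<network_model> d = %d, order = %d, T = %d @ %g Hz, %d regime(s) at t = %s\n",
              dm[3], dm[2], dm[1], x$fs, length(x$regime_bounds),
              paste(x$regime_bounds, collapse = ", ")))
  invisible(x)
}

#' Generate a regime-switching surrogate network
#'
#' Draws a ground-truth time-varying MVAR model: a structural mask over
#' 60-80% of ordered node pairs, directed interactions on a random subset of
#' the structural links, fixed positive AR(2) self-dynamics, and per-regime
#' redraws of the interaction delays, signs and magnitudes. Each regime is
#' rejection-resampled until its companion matrix is stable; for dense large
#' networks, where redraws from the full magnitude grid are essentially never
#' stable, the interaction block is geometrically shrunk (factor 0.95 per
#' step, delay and sign structure preserved) until stability is reached.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A `"network_model"`: `coefficients` `[T x p x d x d]`,
#'   `structural_mask`, `dynamic_mask`, `regime_bounds` (1-based regime start
#'   indices), `fs`.
#' @export
surrogate_network <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config()")
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  d <- cfg$d; p <- cfg$p_true
  Tn <- round(cfg$fs * cfg$duration)
  min_len <- round(cfg$min_regime_sec * cfg$fs)
  if (Tn < cfg$n_regimes * min_len) stop("recording too short for the requested regimes")

  pairs <- which(!diag(d), arr.ind = TRUE)  # ordered (target, source) pairs
  density <- stats::runif(1, cfg$density_range[1], cfg$density_range[2])
  n_struct <- max(1L, round(density * nrow(pairs)))
  struct_idx <- sample.int(nrow(pairs), n_struct)
  structural_mask <- diag(d) > 0
  structural_mask[pairs[struct_idx, , drop = FALSE]] <- TRUE
  n_dyn <- max(1L, round(cfg$dynamic_fraction * n_struct))
  dyn_idx <- sample(struct_idx, n_dyn)
  dynamic_mask <- matrix(FALSE, d, d)
  dynamic_mask[pairs[dyn_idx, , drop = FALSE]] <- TRUE
  links <- pairs[dyn_idx, , drop = FALSE]

  grid <- seq(cfg$coef_range[1], cfg$coef_range[2], by = cfg$coef_step)
  diagA <- array(0, c(p, d, d))
  for (j in seq_len(d)) {
    repeat {  # univariate AR(2) stability for positive pairs: a1 + a2 < 1
      a <- sample(grid, 2L, replace = TRUE)
      if (sum(a) < 1) break
    }
    diagA[1, j, j] <- a[1]
    diagA[2, j, j] <- a[2]
  }

  # regime onsets: uniform composition of the slack above the minimum length
  slack <- Tn - cfg$n_regimes * min_len
  cuts <- sort(sample.int(slack + 1L, cfg$n_regimes - 1L, replace = TRUE) - 1L)
  lens <- diff(c(0L, cuts, slack)) + min_len
  regime_bounds <- cumsum(c(1L, lens[-cfg$n_regimes]))

  coefficients <- array(0, c(Tn, p, d, d))
  for (r in seq_len(cfg$n_regimes)) {
    # rejection sampling first; beyond `shrink_after` failed redraws the
    # interaction block of a fresh draw is geometrically shrunk until the
    # companion matrix is stable (dense large networks with the full
    # magnitude grid are virtually never stable by redraw alone)
    shrink_after <- min(cfg$max_iter, 50L)
    A <- NULL
    for (it in seq_len(shrink_after)) {
      cand <- diagA + draw_offdiag(cfg, links)
      if (is_stable(cand)) { A <- cand; break }
    }
    if (is.null(A)) {
      B <- draw_offdiag(cfg, links)
      for (it in seq_len(cfg$max_iter)) {
        B <- B * 0.95
        if (is_stable(diagA + B)) { A <- diagA + B; break }
      }
    }
    if (is.null(A))
      stop(sprintf("no stable model for regime %d within %d iterations (d = %d, density = %.2f)",
                   r, cfg$max_iter, d, density))
    t0 <- regime_bounds[r]
    t1 <- if (r < cfg$n_regimes) regime_bounds[r + 1L] - 1L else Tn
    for (k in seq_len(p)) coefficients[t0:t1, k, , ] <-
      matrix(rep(A[k, , ], each = t1 - t0 + 1L), ncol = d)
  }
  new_network_model(coefficients, structural_mask, dynamic_mask,
                    regime_bounds, cfg$fs, min_len)
}

# Per-trial shared-component mixture weights giving pairwise noise
# correlations with the requested mean and spread (correlation between trials
# n and m is u_n * u_m).
trial_corr_weights <- function(N, target_mean, target_sd) {
  if (target_mean <= 0) return(rep(0, N))
  mu <- sqrt(target_mean)
  su <- target_sd / (sqrt(2) * mu)
  pmin(pmax(stats::rnorm(N, mu, su), 0), 1)
}

#' Simulate multi-trial time series from a ground-truth model
#'
#' Feeds the time-varying MVAR process with zero-mean unit-variance white
#' generative noise, optionally correlated across trials through a shared
#' noise component, and discards a burn-in of `10 * p` samples.
#'
#' @param model A `"network_model"` (or the `model` element of
#'   [bivariate_demo()]).
#' @param N Number of trials.
#' @param trial_corr Length-2 vector: target mean and sd of pairwise
#'   generative-noise correlations across trials; `NULL` or `c(0, 0)` for
#'   independent trials.
#' @param seed Optional integer seed.
#' @return An [mvts()] `[N x d x T]`.
#' @export
simulate_trials <- function(model, N = 200L, trial_corr = c(0.1, 0.07),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- model$coefficients
  dm <- dim(A); Tn <- dm[1]; p <- dm[2]; d <- dm[3]
  burn <- 10L * p
  Tt <- Tn + burn
  u <- if (is.null(trial_corr)) rep(0, N)
       else trial_corr_weights(N, trial_corr[1], trial_corr[2])
  w <- sqrt(pmax(0, 1 - u^2))
  Y <- array(0, c(N, d, Tt))
  At <- function(t) if (t <= burn) 1L else t - burn  # burn-in uses first regime
  for (t in seq_len(Tt)) {
    g <- stats::rnorm(d)
    eps <- u %o% g + w * matrix(stats::rnorm(N * d), N, d)
    acc <- eps
    for (k in seq_len(min(p, t - 1L)))
      acc <- acc + Y[, , t - k] %*% t(A[At(t), k, , ])
    if (max(abs(acc)) > 1e6)
      stop("divergent trajectory: model instability escaped the checks")
    Y[, , t] <- acc
  }
  mvts(Y[, , (burn + 1L):Tt, drop = FALSE], fs = model$fs)
}

#' Add observation noise at a given signal-to-noise ratio
#'
#' Adds white Gaussian noise scaled per channel so that
#' `mean(signal^2) / mean(noise^2)` equals `snr`.
#'
#' @param Y An [mvts()].
#' @param snr Signal-to-noise ratio (power ratio if `units = "linear"`,
#'   decibels if `units = "db"`). Capped at `1e9`.
#' @param units Interpretation of `snr`.
#' @param seed Optional integer seed.
#' @return A noisy [mvts()].
#' @export
add_observation_noise <- function(Y, snr, units = c("linear", "db"),
                                  seed = NULL) {
  units <- match.arg(units)
  if (units == "db") snr <- 10^(snr / 10)
  if (snr <= 0) stop("`snr` must be positive")
  snr <- min(snr, 1e9)
  if (!is.null(seed)) set.seed(seed)
  cube <- as_cube(Y)
  dm <- dim(cube)
  for (ch in seq_len(dm[2])) {
    sd_noise <- sqrt(mean(cube[, ch, ]^2) / snr)
    cube[, ch, ] <- cube[, ch, ] +
      sd_noise * array(stats::rnorm(dm[1] * dm[3]), c(dm[1], dm[3]))
  }
  if (inherits(Y, "mvts")) { Y$data <- cube; Y } else cube
}

#' Random node positions on a square grid
#'
#' @param d Number of nodes.
#' @param extent Side length of the square in mm (default 150).
#' @param seed Optional integer seed.
#' @return `[d x 2]` matrix of positions in mm.
#' @export
random_positions <- function(d, extent = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(2 * d, 0, extent), d, 2)
}

#' Instantaneous spatial mixing (leakage) of channels
#'
#' Convolves the channels at every time point with a Gaussian point-spread
#' kernel: mixing weights `M[i, j] = exp(-||pos_i - pos_j||^2 / (2 sigma^2))`
#' with each row normalized to unit sum.
#'
#' @param Y An [mvts()].
#' @param positions `[d x 2]` node positions in mm.
#' @param sigma Kernel standard deviation in mm.
#' @return The mixed [mvts()].
#' @export
apply_spatial_mixing <- function(Y, positions, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive")
  cube <- as_cube(Y)
  d <- dim(cube)[2]
  if (!is.matrix(positions) || nrow(positions) != d || ncol(positions) != 2L)
    stop("`positions` must be a [d x 2] matrix")
  D2 <- as.matrix(stats::dist(positions))^2
  M <- exp(-D2 / (2 * sigma^2))
  M <- M / rowSums(M)
  for (t in seq_len(dim(cube)[3]))
    cube[, , t] <- cube[, , t] %*% t(M)
  if (inherits(Y, "mvts")) { Y$data <- cube; Y } else cube
}

#' Two-node coupling demonstration
#'
#' A bivariate AR(1) process with fixed self-coefficients and a transient
#' directed coupling from node 2 to node 1 (`A[1, 2]`) switched on inside a
#' window and zero outside; `A[2, 1]` is always zero. This is the canonical
#' test of tracking speed versus smoothness for adaptive filters.
#'
#' @param samples Number of time samples.
#' @param fs Sampling rate (Hz).
#' @param trials Number of trials.
#' @param diag_coef Self-coupling of both nodes (default 0.9).
#' @param coupling Directed coupling `A[1, 2]` inside the window (default 0.5).
#' @param window Length-2 integer vector: first and last sample (1-based) of
#'   the active coupling.
#' @param seed Optional integer seed.
#' @return List with `Y` (an [mvts()]) and `model` (a `"network_model"`
#'   holding the true coefficients and masks).
#' @export
bivariate_demo <- function(samples = 1000L, fs = 200, trials = 200L,
                           diag_coef = 0.9, coupling = 0.5,
                           window = c(401L, 600L), seed = NULL) {
  if (window[1] < 2L || window[2] > samples || window[1] > window[2])
    stop("`window` must lie within the recording")
  A <- array(0, c(samples, 1L, 2L, 2L))
  A[, 1, 1, 1] <- diag_coef
  A[, 1, 2, 2] <- diag_coef
  A[window[1]:window[2], 1, 1, 2] <- coupling
  if (!is_stable(array(A[window[1], 1, , ], c(1, 2, 2))) ||
      !is_stable(array(A[1, 1, , ], c(1, 2, 2))))
    stop("unstable parameter combination")
  structural <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)  # diag + (1 <- 2)
  dynamic <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)
  model <- structure(list(coefficients = A, structural_mask = structural,
                          dynamic_mask = dynamic,
                          regime_bounds = c(1L, window[1], window[2] + 1L),
                          fs = fs, order = 1L),
                     class = "network_model")
  Y <- simulate_trials(model, N = trials, trial_corr = NULL, seed = seed)
  list(Y = Y, model = model)
}
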