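# Hand-built PDC-like tensors for ROC tests.
toy_tensor <- function(vals, d, Fq, Tn) array(vals, c(d, d, Fq, Tn))

test_that("ground-truth PDC reflects the generating masks", {
  # no dynamic links: all off-diagonal ground-truth PDC is zero
  cfg <- sim_config(d = 4, duration = 0.8)
  model <- surrogate_network(cfg, seed = 3)
  for (l in 1:4) for (j in 1:4) if (l != j)
    model$coefficients[, , l, j] <- 0  # strip interactions
  model$dynamic_mask[] <- FALSE
  gt <- pdc(model, freqs = c(10, 40))
  off <- !diag(4)
  expect_true(all(apply(gt$values, c(3, 4), function(m) all(m[off] == 0))))

  # nonzero cells appear only where the dynamic mask allows
  model2 <- surrogate_network(cfg, seed = 9)
  gt2 <- ground_truth_pdc(model2, freqs = c(10, 40))
  nz <- apply(gt2$values > 1e-12, c(1, 2), any)
  expect_true(all(!nz[off] | model2$dynamic_mask[off]))
})

test_that("ROC is perfect for the truth and chance for noise", {
  set.seed(50)
  gt <- toy_tensor(rbinom(3 * 3 * 5 * 20, 1, 0.3) * runif(900), 3, 5, 20)
  expect_equal(roc_auc(gt, gt)$auc, 1)

  aucs <- replicate(20, {
    est <- toy_tensor(runif(900), 3, 5, 20)
    roc_auc(gt, est)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  expect_error(roc_auc(toy_tensor(1, 3, 5, 20), toy_tensor(1, 3, 5, 20)),
               "all-absent or all-present")
})

test_that("confusion counts match a hand-enumerable 3x3 toy", {
  # one true connection (target 1 <- source 2) at a single (f, t)
  gt <- toy_tensor(0, 3, 1, 1); gt[1, 2, 1, 1] <- 0.8
  est <- toy_tensor(0, 3, 1, 1)
  est[1, 2, 1, 1] <- 0.9   # the true link, ranked first
  est[2, 3, 1, 1] <- 0.4   # a false alarm below it
  r <- roc_auc(gt, est)
  # 6 off-diagonal cells: 1 positive, 5 negatives; criteria are quantiles of
  # the est distribution {0.9, 0.4, 0, 0, 0, 0}
  expect_equal(r$n, 6L)
  naive_sens <- sapply(r$thresholds, function(th)
    sum(est[1, 2, 1, 1] > th) / 1)
  naive_spec <- sapply(r$thresholds, function(th) {
    fp <- sum(c(est[2, 3, 1, 1], 0, 0, 0, 0) > th)
    (5 - fp) / 5
  })
  expect_equal(r$sensitivity, naive_sens)
  expect_equal(r$specificity, naive_spec)
})

test_that("quantile-criterion ROC agrees with an exhaustive threshold sweep", {
  set.seed(51)
  for (i in 1:5) {
    gt <- toy_tensor(rbinom(4 * 4 * 6 * 15, 1, 0.4) * runif(1440), 4, 6, 15)
    est <- toy_tensor(pmax(0, as.numeric(gt) * 2 + rnorm(1440, sd = 0.5)),
                      4, 6, 15)
    r <- roc_auc(gt, est)
    # oracle: 1000 evenly spaced thresholds over the estimate's range
    gx <- dynstok:::offdiag_cells(gt) > 1e-12
    ex <- dynstok:::offdiag_cells(est)
    thr <- seq(min(ex) - 1e-9, max(ex), length.out = 1000)
    tpr <- sapply(thr, function(th) sum(ex > th & gx) / sum(gx))
    fpr <- sapply(thr, function(th) sum(ex > th & !gx) / sum(!gx))
    oo <- order(fpr, tpr)
    fpr <- c(0, fpr[oo], 1); tpr <- c(0, tpr[oo], 1)
    auc_oracle <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_lt(abs(r$auc - auc_oracle), 0.01)
  }
})

test_that("AUC is invariant under monotone transforms of the estimate", {
  set.seed(52)
  gt <- toy_tensor(rbinom(3 * 3 * 4 * 10, 1, 0.35) * runif(360), 3, 4, 10)
  est <- toy_tensor(runif(360), 3, 4, 10)
  a0 <- roc_auc(gt, est)$auc
  expect_equal(roc_auc(gt, toy_tensor(as.numeric(est)^2, 3, 4, 10))$auc, a0)
  expect_equal(roc_auc(gt, toy_tensor(exp(3 * as.numeric(est)), 3, 4, 10))$auc,
               a0)
})

test_that("the quantile_0.5 rule binarizes against the truth's median", {
  set.seed(57)
  gt <- toy_tensor(runif(360), 3, 4, 10)
  est <- toy_tensor(as.numeric(gt) + rnorm(360, sd = 0.1), 3, 4, 10)
  r <- roc_auc(gt, est, gt_rule = "quantile_0.5")
  expect_gt(r$auc, 0.8)  # estimate tracks the truth
  gx <- dynstok:::offdiag_cells(gt)
  expect_equal(r$n, length(gx))
})

test_that("strongest-connection subsetting keeps half the true links", {
  set.seed(53)
  gt <- toy_tensor(rbinom(5 * 5 * 4 * 12, 1, 0.3) * runif(1200), 5, 4, 12)
  est <- toy_tensor(runif(1200), 5, 4, 12)
  sub <- strongest_connections(gt, est, q = 0.5)
  nz_before <- sum(dynstok:::offdiag_cells(gt) > 1e-12)
  nz_after <- sum(sub$gt > 1e-12)
  expect_lte(abs(nz_after - nz_before / 2), 1)
  # zero (absent) cells all survive as negatives
  expect_equal(sum(sub$gt <= 1e-12),
               sum(dynstok:::offdiag_cells(gt) <= 1e-12))
  # composition with roc_auc runs
  expect_s3_class(roc_auc(sub$gt, sub$est), "roc_result")

  # degenerate single-link case: every active cell is tied at the median
  gt1 <- toy_tensor(0, 3, 1, 8); gt1[1, 2, 1, 3:6] <- 0.4
  est1 <- toy_tensor(runif(72), 3, 1, 8)
  sub1 <- strongest_connections(gt1, est1)
  expect_equal(sum(sub1$gt > 0), 4L)  # all retained
})

test_that("summed flows add band-averaged PDC over partners", {
  vals <- array(0, c(3, 3, 4, 5))
  vals[2, 1, , ] <- 0.6  # single link: node 1 drives node 2
  fake <- structure(list(values = vals, freqs = c(10, 20, 30, 40), fs = 200,
                         kind = "pdc"), class = "spectral_connectivity")
  out <- summed_flow(fake, band = c(10, 40), kind = "outflow")
  expect_equal(out$values[1, ], rep(0.6, 5))
  expect_equal(out$values[2, ], rep(0, 5))
  inf <- summed_flow(fake, band = c(10, 40), kind = "inflow")
  expect_equal(inf$values[2, ], rep(0.6, 5))
  expect_error(summed_flow(fake, band = c(90, 95)), "band")

  # conservation: total outflow equals total inflow at every time
  set.seed(54)
  rnd <- structure(list(values = array(runif(3 * 3 * 4 * 5), c(3, 3, 4, 5)),
                        freqs = c(10, 20, 30, 40), fs = 200, kind = "pdc"),
                   class = "spectral_connectivity")
  o <- summed_flow(rnd, band = c(10, 30))$values
  i <- summed_flow(rnd, band = c(10, 30), kind = "inflow")$values
  expect_equal(colSums(o), colSums(i), tolerance = 1e-12)
})

test_that("gamma outflow of the demo driver steps up inside the window", {
  demo <- get_demo()
  gt <- ground_truth_pdc(demo$model, freqs = seq(40, 90, by = 5))
  flow <- summed_flow(gt, band = c(40, 90), kind = "outflow")
  expect_gt(min(flow$values[2, 401:600]), max(flow$values[2, c(1:400, 601:1000)]))
  expect_true(all(flow$values[1, ] == 0))  # node 1 never drives
})

test_that("baseline z-scoring centers and scales exactly", {
  tm <- seq(-0.2, 0.3, by = 0.05)
  x <- matrix(rep(3, length(tm)), 1)
  expect_true(all(is.na(suppressWarnings(baseline_zscore(x, tm)))) ||
              all(suppressWarnings(baseline_zscore(x, tm)) == 0))
  expect_warning(baseline_zscore(x, tm), "zero baseline sd")

  # hand series: baseline samples (in -0.1..0) have mean 2, sd 1
  x2 <- matrix(0, 1, length(tm))
  base_idx <- which(tm >= -0.1 & tm <= 0)
  x2[1, base_idx] <- c(1, 2, 3)[seq_along(base_idx)]
  x2[1, tm > 0] <- 5
  z <- baseline_zscore(x2, tm)
  expect_equal(as.numeric(z[1, tm > 0]), rep((5 - 2) / 1, sum(tm > 0)))
  expect_error(baseline_zscore(x2, tm, baseline = c(-0.2, -0.19)), "3 samples")
})

test_that("global connectivity averages the directed pairs", {
  x <- array(2.5, c(3, 3, 4, 6))
  expect_equal(global_connectivity(x), matrix(2.5, 4, 6))
  x2 <- array(0, c(2, 2, 1, 3))
  x2[1, 2, 1, ] <- c(1, 2, 3); x2[2, 1, 1, ] <- c(3, 2, 1)
  expect_equal(global_connectivity(x2), matrix(2, 1, 3))
})

test_that("bootstrap difference test separates clear effects from nulls", {
  set.seed(56)
  S <- 10; Tn <- 12
  ref <- matrix(rnorm(S * Tn), S, Tn)
  null <- bootstrap_difference_test(ref, ref, n_boot = 2000, seed = 1)
  expect_true(all(!null$significant))
  expect_true(all(null$p_values == 1))

  shifted <- ref + 10 * sd(ref)
  alt <- bootstrap_difference_test(shifted, ref, n_boot = 2000, seed = 1)
  expect_true(all(alt$significant))
  expect_true(all(alt$p_values >= 1 / 2000))  # add-one floor
  expect_error(bootstrap_difference_test(ref[1:2, ], ref[1:2, ]), "3 subjects")
})
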