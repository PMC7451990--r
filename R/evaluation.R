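# Validation machinery: ground-truth PDC, quantile-criterion ROC/AUC,
# band-limited summed flows, baseline z-scoring, global connectivity, and a
# subject-level bootstrap difference test.

#' Ground-truth PDC of a simulated network
#'
#' Applies [pdc()] directly to the true time-varying coefficients of a
#' `"network_model"`, giving the target connectivity against which estimates
#' are scored.
#'
#' @param model A `"network_model"`.
#' @param freqs Frequencies in Hz (default 1-100 Hz clipped to Nyquist).
#' @return A `"spectral_connectivity"` of kind `"pdc"`.
#' @export
ground_truth_pdc <- function(model, freqs = NULL) {
  if (!inherits(model, "network_model")) stop("`model` must be a network_model")
  pdc(model, freqs)
}

# Pool the off-diagonal (target, source, f, t) cells of a PDC tensor into a
# numeric vector (diagonal self-influence excluded).
offdiag_cells <- function(x) {
  if (inherits(x, "spectral_connectivity")) x <- x$values
  if (is.numeric(x) && is.null(dim(x))) return(as.numeric(x))
  dm <- dim(x)
  if (length(dm) != 4L || dm[1] != dm[2]) stop("expected a [d x d x F x T] tensor")
  d <- dm[1]
  m <- matrix(x, nrow = d * d)
  as.numeric(m[which(!diag(d)), ])
}

#' Quantile-criterion ROC curve and AUC
#'
#' Scores an estimated PDC tensor against ground truth by detection theory.
#' Ground truth is binarized over the pooled off-diagonal
#' `(target, source, f, t)` cells (connections larger than zero present, or
#' larger than the ground truth's own median); the estimate is binarized at
#' `n_criteria` equally spaced quantile criteria of its pooled off-diagonal
#' distribution (1st to 99th percentile). Sensitivity and specificity at each
#' criterion give the ROC curve; the area under it (trapezoid rule, with
#' anchors at (0,0) and (1,1)) summarizes detection performance.
#'
#' @param gt Ground-truth PDC: a `"spectral_connectivity"`, a
#'   `[d x d x F x T]` array, or an already-pooled numeric vector.
#' @param est Estimated PDC in the same form (cells must align with `gt`).
#'   `NA` cells (e.g. the filter warm-up) are dropped pairwise.
#' @param gt_rule Binarization rule for the ground truth.
#' @param n_criteria Number of quantile criteria (default 20).
#' @return A `"roc_result"`: quantile levels, thresholds, `sensitivity`,
#'   `specificity`, `auc`, the rule used, and the number of pooled cells `n`.
#' @export
roc_auc <- function(gt, est, gt_rule = c("greater_than_zero", "quantile_0.5"),
                    n_criteria = 20L) {
  gt_rule <- match.arg(gt_rule)
  gx <- offdiag_cells(gt)
  ex <- offdiag_cells(est)
  if (length(gx) != length(ex)) stop("ground truth and estimate shapes differ")
  if (anyNA(gx) || anyNA(ex) || any(is.infinite(gx)) || any(is.infinite(ex))) {
    keep <- is.finite(gx) & is.finite(ex)
    gx <- gx[keep]; ex <- ex[keep]
  }
  if (length(gx) == 0L) stop("no jointly finite cells")
  gtb <- if (gt_rule == "greater_than_zero") gx > 1e-12
         else gx > stats::quantile(gx, 0.5, names = FALSE)
  P <- sum(gtb); Nn <- length(gtb) - P
  if (P == 0L || Nn == 0L)
    stop("undefined ROC: ground truth is all-absent or all-present")
  levels <- seq(0.01, 0.99, length.out = n_criteria)
  # type-7 sample quantiles from one full sort (quantile() re-sorts per probe)
  sx <- sort(ex, method = "quick")
  n <- length(sx)
  h <- (n - 1) * levels + 1
  lo <- floor(h)
  thr <- sx[lo] + (h - lo) * (sx[pmin(lo + 1L, n)] - sx[lo])
  rm(sx)
  # bins[i] = number of thresholds strictly below ex[i]; criterion j predicts
  # "present" iff ex > thr[j] iff bins >= j
  bins <- findInterval(ex, thr, left.open = TRUE)
  cnt_pos <- tabulate(bins[gtb] + 1L, nbins = n_criteria + 1L)
  cnt_all <- tabulate(bins + 1L, nbins = n_criteria + 1L)
  above_pos <- rev(cumsum(rev(cnt_pos)))  # [j+1] = positives with bins >= j
  above_all <- rev(cumsum(rev(cnt_all)))
  j <- seq_len(n_criteria)
  tp <- above_pos[j + 1L]
  fp <- above_all[j + 1L] - tp
  sens <- tp / P
  spec <- (Nn - fp) / Nn
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(criteria = levels, thresholds = thr, sensitivity = sens,
                 specificity = spec, auc = auc, gt_rule = gt_rule,
                 n = length(gtb)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d pooled cells (%d criteria, rule = %s)\n",
              x$auc, x$n, length(x$criteria), x$gt_rule))
  invisible(x)
}

#' Restrict ROC scoring to the strongest true connections
#'
#' Keeps the absent (zero ground-truth) cells plus the present cells whose
#' ground-truth magnitude exceeds the `q`-quantile of the nonzero cells, the
#' protocol for asking whether an estimator's errors concentrate on weak
#' links.
#'
#' @inheritParams roc_auc
#' @param q Quantile of the nonzero ground-truth magnitudes (default 0.5).
#' @return List with pooled vectors `gt` and `est`, directly usable by
#'   [roc_auc()].
#' @export
strongest_connections <- function(gt, est, q = 0.5) {
  gx <- offdiag_cells(gt)
  ex <- offdiag_cells(est)
  if (length(gx) != length(ex)) stop("ground truth and estimate shapes differ")
  keep <- is.finite(gx) & is.finite(ex)
  gx <- gx[keep]; ex <- ex[keep]
  nz <- gx > 1e-12
  if (!any(nz)) stop("no nonzero ground-truth cells")
  thr <- stats::quantile(gx[nz], q, names = FALSE)
  sel <- !nz | gx >= thr  # >= keeps tied cells (e.g. a single repeated link)
  if (!any(gx[sel] > 1e-12)) stop("empty strongest-connection subset")
  list(gt = gx[sel], est = ex[sel])
}

#' Band-limited summed connectivity flow per node
#'
#' Per-node driving strength over time: the outflow of node `j` at time `t`
#' is the sum over targets `l != j` of the band-averaged PDC `[l, j, f, t]`
#' (inflow sums over sources instead).
#'
#' @param pdc_obj A `"spectral_connectivity"` of kind `"pdc"`.
#' @param band Length-2 frequency band in Hz (default 40-90 Hz, the gamma
#'   band of the rodent benchmark protocol).
#' @param kind `"outflow"` or `"inflow"`.
#' @return A `"flow_series"`: `values` `[d x T]`, `band`, `kind`.
#' @export
summed_flow <- function(pdc_obj, band = c(40, 90),
                        kind = c("outflow", "inflow")) {
  kind <- match.arg(kind)
  if (!inherits(pdc_obj, "spectral_connectivity") || pdc_obj$kind != "pdc")
    stop("`pdc_obj` must be a PDC spectral_connectivity")
  sel <- which(pdc_obj$freqs >= band[1] & pdc_obj$freqs <= band[2])
  if (length(sel) == 0L) stop("no frequencies inside the requested band")
  v <- pdc_obj$values[, , sel, , drop = FALSE]
  dm <- dim(v); d <- dm[1]; Tn <- dm[4]
  bm <- array(0, c(d, d, Tn))
  for (f in seq_along(sel)) bm <- bm + v[, , f, ]
  bm <- bm / length(sel)
  for (j in seq_len(d)) bm[j, j, ] <- 0  # exclude self-influence
  vals <- if (kind == "outflow") apply(bm, c(2, 3), sum) else apply(bm, c(1, 3), sum)
  structure(list(values = vals, band = band, kind = kind),
            class = "flow_series")
}

#' Z-score a time-resolved tensor against a baseline period
#'
#' Standardizes every series (all leading dimensions; time last) by the mean
#' and standard deviation of the samples falling inside the baseline
#' interval.
#'
#' @param x Numeric array whose last dimension is time (a plain matrix
#'   `[anything x T]` also works).
#' @param time Time axis in seconds (length `T`; may be negative
#'   pre-stimulus).
#' @param baseline Length-2 interval in seconds, inclusive (default -0.1 to
#'   0 s, i.e. the 100 ms before stimulus onset). Must contain >= 3 samples.
#' @return Array of the same shape; series with zero baseline sd become `NaN`
#'   with a warning.
#' @export
baseline_zscore <- function(x, time, baseline = c(-0.1, 0)) {
  dm <- dim(x)
  if (is.null(dm)) { x <- matrix(x, 1); dm <- dim(x) }
  Tn <- dm[length(dm)]
  if (length(time) != Tn) stop("`time` must match the last dimension of `x`")
  idx <- which(time >= baseline[1] & time <= baseline[2])
  if (length(idx) < 3L) stop("baseline must contain at least 3 samples")
  m <- matrix(x, ncol = Tn)
  mu <- rowMeans(m[, idx, drop = FALSE])
  sd0 <- apply(m[, idx, drop = FALSE], 1, stats::sd)
  if (any(sd0 == 0, na.rm = TRUE))
    warning("zero baseline sd in some series; z-scores set to NaN", call. = FALSE)
  sd0[sd0 == 0] <- NaN
  z <- (m - mu) / sd0
  array(z, dm)
}

#' Global connectivity over time and frequency
#'
#' Averages a (typically baseline z-scored) PDC tensor over all off-diagonal
#' directed pairs, yielding one time-frequency matrix summarizing
#' network-wide connectivity dynamics.
#'
#' @param x `[d x d x F x T]` array (or a `"spectral_connectivity"`).
#' @param na_rm Drop `NA` cells from the average.
#' @return `[F x T]` matrix.
#' @export
global_connectivity <- function(x, na_rm = FALSE) {
  if (inherits(x, "spectral_connectivity")) x <- x$values
  dm <- dim(x)
  if (length(dm) != 4L || dm[1] != dm[2]) stop("expected a [d x d x F x T] tensor")
  d <- dm[1]
  m <- matrix(x, nrow = d * d)  # rows = (l, j), cols = (f, t)
  off <- m[which(!diag(d)), , drop = FALSE]
  matrix(colMeans(off, na.rm = na_rm), dm[3], dm[4])
}

#' Bootstrap difference test across subjects at each time point
#'
#' At each time point, resamples subjects with replacement and builds the
#' bootstrap distribution of the mean difference between two per-subject
#' series (e.g. the summed outflow of a candidate driver versus the second
#' largest driver). The two-sided p-value is twice the fraction of bootstrap
#' means on the non-dominant side of zero, floored at `1 / n_boot`.
#'
#' @param samples,reference Numeric matrices `[S subjects x T]`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param alpha Significance level for the reported mask.
#' @param seed Optional integer seed.
#' @return List with `p_values` (length `T`), `significant` (logical mask
#'   `p < alpha`), `alpha`, `n_boot`.
#' @export
bootstrap_difference_test <- function(samples, reference, n_boot = 10000L,
                                      alpha = 0.05, seed = NULL) {
  if (!is.matrix(samples) || !is.matrix(reference) ||
      !all(dim(samples) == dim(reference)))
    stop("`samples` and `reference` must be [S x T] matrices of equal shape")
  S <- nrow(samples); Tn <- ncol(samples)
  if (S < 3L) stop("need at least 3 subjects")
  if (!is.null(seed)) set.seed(seed)
  D <- samples - reference
  p <- numeric(Tn)
  for (t in seq_len(Tn)) {
    dt <- D[, t]
    if (max(dt) == min(dt) && dt[1] == 0) { p[t] <- 1; next }
    idx <- matrix(sample.int(S, S * n_boot, replace = TRUE), n_boot, S)
    bm <- rowMeans(matrix(dt[idx], n_boot, S))
    p[t] <- min(1, max(2 * min(mean(bm <= 0), mean(bm >= 0)), 1 / n_boot))
  }
  list(p_values = p, significant = p < alpha, alpha = alpha, n_boot = n_boot)
}
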