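#' Build the lag (measurement) matrix at one time point
#'
#' Stacks the `p` most recent past samples of every trial into the regression
#' design matrix used by both filters: `H_t = (Y_{t-1}, ..., Y_{t-p})`, with
#' trials as rows. Column block `k` (width `d`) holds all trials of the process
#' at time `t - k`.
#'
#' @param Y An [mvts()] or a 3-d array `[N x d x T]`.
#' @param t Time index (1-based). Must satisfy `t >= p + 1`.
#' @param p Model order (number of lags), `p >= 1`.
#' @return Numeric matrix `[N x d*p]`.
#' @export
build_lag_matrix <- function(Y, t, p) {
  cube <- as_cube(Y)
  dm <- dim(cube)
  if (p < 1L) stop("`p` must be >= 1")
  if (t > dm[3]) stop("`t` beyond the end of the series")
  if (t <= p)
    stop(sprintf("lag window underflow: t = %d needs %d past samples; earliest valid t is %d",
                 t, p, p + 1L))
  N <- dm[1]; d <- dm[2]
  H <- matrix(0, N, d * p)
  for (k in seq_len(p))
    H[, ((k - 1L) * d + 1L):(k * d)] <- cube[, , t - k, drop = TRUE]
  if (N == 1L) H <- matrix(H, nrow = 1L)  # drop=TRUE collapses the trial dim
  H
}

#' Convert between the stacked state matrix and AR coefficient matrices
#'
#' The filters carry the tvMVAR coefficients as a single `[d*p x d]` state
#' matrix `x` whose rows `(k-1)d + 1 ... kd` hold the transpose of the lag-`k`
#' coefficient matrix: `A_k[l, j] = x[(k-1)d + j, l]`. The two functions are
#' exact inverses.
#'
#' @param x State matrix `[d*p x d]`.
#' @param d Number of channels.
#' @param p Model order.
#' @return `state_to_coefficients()`: array `[p x d x d]` with entry
#'   `[k, l, j]` the lag-`k` influence of channel `j` on channel `l`.
#'   `coefficients_to_state()`: the `[d*p x d]` state matrix.
#' @examples
#' x <- matrix(c(0.9, 0, 0.5, 0.9), 2, 2)
#' state_to_coefficients(x, d = 2, p = 1)[1, , ]
#' @export
state_to_coefficients <- function(x, d, p) {
  if (!is.matrix(x) || nrow(x) != d * p || ncol(x) != d)
    stop(sprintf("state matrix must be [%d x %d]", d * p, d))
  A <- array(0, c(p, d, d))
  for (k in seq_len(p))
    A[k, , ] <- t(x[((k - 1L) * d + 1L):(k * d), , drop = FALSE])
  A
}

#' @param A Coefficient array `[p x d x d]`.
#' @rdname state_to_coefficients
#' @export
coefficients_to_state <- function(A) {
  dm <- dim(A)
  if (length(dm) != 3L || dm[2] != dm[3]) stop("`A` must be [p x d x d]")
  p <- dm[1]; d <- dm[2]
  x <- matrix(0, d * p, d)
  for (k in seq_len(p))
    x[((k - 1L) * d + 1L):(k * d), ] <- t(A[k, , ])
  x
}

#' Select the MVAR model order by Akaike's final prediction error
#'
#' Fits a stationary MVAR by pooled ordinary least squares (trials as
#' independent regression rows) on a time window, for each candidate order,
#' and returns the order minimizing
#' `FPE(p) = det(Sigma_eps(p)) * ((M + d*p + 1) / (M - d*p - 1))^d`,
#' where `M` is the number of regression rows. For `d = 1` this reduces to the
#' classical univariate FPE.
#'
#' @param Y An [mvts()] or 3-d array.
#' @param window Integer vector of time indices to fit on (default: all).
#' @param p_max Largest candidate order.
#' @return The selected order (integer). The FPE curve is attached as
#'   attribute `"fpe"` (named numeric vector; `NA` for skipped orders).
#' @export
select_order_fpe <- function(Y, window = NULL, p_max = 10L) {
  cube <- as_cube(Y)
  dm <- dim(cube); N <- dm[1]; d <- dm[2]; Tn <- dm[3]
  if (is.null(window)) window <- seq_len(Tn)
  window <- sort(as.integer(window))
  if (p_max < 1L) stop("`p_max` must be >= 1")
  fpe <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    tt <- window[window >= p + 1L]
    M <- N * length(tt)
    if (M <= d * p + 1L) next  # FPE correction factor undefined
    H <- do.call(rbind, lapply(tt, function(t) build_lag_matrix(cube, t, p)))
    Z <- do.call(rbind, lapply(tt, function(t) matrix(cube[, , t], N, d)))
    fit <- tryCatch(qr(H), error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(H)) {
      warning(sprintf("order p = %d skipped: ill-conditioned regression", p))
      next
    }
    E <- Z - H %*% qr.coef(fit, Z)
    Sigma <- crossprod(E) / M
    fpe[p] <- det(Sigma) * ((M + d * p + 1) / (M - d * p - 1))^d
  }
  if (all(!is.finite(fpe))) stop("FPE undefined at every candidate order")
  best <- which.min(fpe)
  names(fpe) <- seq_len(p_max)
  structure(as.integer(best), fpe = fpe)
}
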