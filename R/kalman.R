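# General linear Kalman filter for multi-trial tvMVAR estimation.
#
# State-space form: identity transition (first-order random walk on the
# coefficients), process noise replaced by a rate-of-change term C^2 * I on
# the predicted error covariance, and measurement noise replaced by the trace
# of a recursively updated innovation covariance. A single adaptation
# constant c (tied to C by default) sets the tracking-speed / smoothness
# trade-off.

# Symmetric positive-definite solve of S X = B with pseudo-inverse fallback
# for near-singular innovation matrices (e.g. strongly correlated trials).
solve_spd <- function(S, B, cond_tol = 1e12) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) {
    dg <- diag(ch)
    if ((max(dg) / min(dg))^2 < cond_tol)
      return(backsolve(ch, backsolve(ch, B, transpose = TRUE)))
  }
  warning("near-singular innovation covariance; using pseudo-inverse", call. = FALSE)
  sv <- svd(S)
  pos <- sv$d > max(dim(S)) * .Machine$double.eps * sv$d[1]
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, B))
}

#' General linear Kalman filter for time-varying MVAR coefficients
#'
#' Recursively estimates the time-varying MVAR coefficients of a multi-trial
#' process. At each time `t` (from `p + 1`): predict with identity transition
#' and inflate the error covariance by `C^2 * I`; form the innovations
#' `E = z_t - H_t x`; update the measurement-noise proxy
#' `R_t = R_{t-1} + c * (E'E/(N-1) - R_{t-1})`; compute the gain
#' `K = P H' (H P H' + tr(R_t) I_N)^{-1}`; update state and covariance.
#'
#' @param Y An [mvts()] or 3-d array `[N x d x T]`, `N >= 2`.
#' @param p Model order in samples.
#' @param c Adaptation constant in `(0, 1]` controlling how fast the
#'   measurement-noise estimate and the error covariance adapt.
#' @param C Rate-of-change constant for the predicted error covariance;
#'   defaults to `c` (the two are tied unless overridden).
#' @param x0,P0,R0 Optional initial state `[d*p x d]`, error covariance
#'   `[d*p x d*p]` and measurement-noise estimate `[d x d]`; defaults are the
#'   zero matrix, identity and identity.
#' @return A `"tvmvar"` estimate with constant `c_trajectory`, the `R_t`
#'   sequence in `innovation_cov`, and the relative error variance of the
#'   one-step predictions in field `rev`.
#' @seealso [stok_filter()], [tune_kf_c()]
#' @export
kf_filter <- function(Y, p, c = 0.02, C = c, x0 = NULL, P0 = NULL, R0 = NULL) {
  cube <- as_cube(Y)
  if (!all(is.finite(cube))) stop("non-finite values in input")
  dm <- dim(cube); N <- dm[1]; d <- dm[2]; Tn <- dm[3]
  if (N < 2L) stop("need N >= 2 trials (innovation covariance uses N - 1)")
  if (Tn <= p) stop("need T > p")
  if (c <= 0 || c > 1) stop("`c` must be in (0, 1]")
  dp <- d * p
  x <- if (is.null(x0)) matrix(0, dp, d) else x0
  P <- if (is.null(P0)) diag(dp) else P0
  Rhat <- if (is.null(R0)) diag(d) else R0
  stopifnot(all(dim(x) == c(dp, d)), all(dim(P) == c(dp, dp)),
            all(dim(Rhat) == c(d, d)))
  Idp <- diag(dp)
  coef <- array(NA_real_, c(Tn, p, d, d))
  icov <- array(NA_real_, c(Tn, d, d))
  rev_num <- 0; rev_den <- 0
  for (t in (p + 1L):Tn) {
    H <- build_lag_matrix(cube, t, p)
    z <- matrix(cube[, , t], N, d)
    # predict (identity transition, rate-of-change inflation)
    P <- P + C^2 * Idp
    E <- z - H %*% x
    Sr <- crossprod(E) / (N - 1)
    Rhat <- Rhat + c * (Sr - Rhat)
    PHt <- P %*% t(H)
    S <- H %*% PHt
    diag(S) <- diag(S) + sum(diag(Rhat))
    K <- t(solve_spd(S, t(PHt)))
    x <- x + K %*% E
    P <- P - K %*% t(PHt)
    P <- (P + t(P)) / 2
    coef[t, , , ] <- state_to_coefficients(x, d, p)
    icov[t, , ] <- Rhat
    rev_num <- rev_num + sum(E^2)
    rev_den <- rev_den + sum(z^2)
  }
  fs <- if (inherits(Y, "mvts")) Y$fs else NA_real_
  new_tvmvar(coef, as.integer(p), icov, rep(c, Tn), fs, "kf",
             extra = list(rev = rev_num / rev_den, C = C))
}

#' Tune the Kalman adaptation constant by relative error variance
#'
#' Runs [kf_filter()] over a grid of adaptation constants and selects the one
#' minimizing the relative error variance of the one-step predictions,
#' `REV(c) = sum_t ||z_t - H_t x_t^-||_F^2 / sum_t ||z_t||_F^2`, over the
#' valid time range. Ties resolve to the smallest `c`.
#'
#' @inheritParams kf_filter
#' @param c_grid Numeric vector of candidate constants in `(0, 1]`.
#' @return List with `c` (selected constant) and `rev` (data frame of the grid
#'   and its REV values).
#' @export
tune_kf_c <- function(Y, p, c_grid) {
  if (length(c_grid) < 1L) stop("`c_grid` must be nonempty")
  if (any(c_grid <= 0 | c_grid > 1)) stop("grid values must be in (0, 1]")
  rev <- vapply(c_grid, function(cc) kf_filter(Y, p, c = cc)$rev, numeric(1))
  if (all(!is.finite(rev))) stop("REV non-finite for every grid value")
  ord <- order(rev, c_grid)  # ties -> smallest c
  list(c = c_grid[ord[1]], rev = data.frame(c = c_grid, rev = rev))
}
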