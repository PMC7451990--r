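# Self-Tuning Optimized Kalman filter (STOK).
#
# Replaces the noise-covariance machinery of the classical filter with a
# regularized least-squares gain: the state update is an exponential moving
# average between the previous state and the instantaneous least-squares
# coefficients H^+ z, with the pseudo-inverse damped by SVD filter factors
# chosen to retain a fixed fraction of the design-matrix variance, and the
# averaging weight c_t re-tuned at every sample from the ratio of innovation
# residuals in two consecutive non-overlapping windows of length p.

#' Damped SVD pseudo-inverse
#'
#' Computes a regularized Moore-Penrose pseudo-inverse of the lag matrix via
#' its thin SVD `H = U S V'`. The squared singular values are treated as the
#' energy spectrum; the damping parameter `lambda` is the squared first
#' singular value *excluded* from the smallest set retaining at least a
#' `theta` fraction of total energy (0 when all components are retained).
#' Each singular component is then weighted by the filter factor
#' `s / (s^2 + lambda)`, which shrinks weak components instead of truncating
#' them; zero singular values contribute zero.
#'
#' @param H Numeric matrix `[N x d*p]`, finite and not all zero.
#' @param theta Fraction of total variance (energy) to retain, in `(0, 1]`.
#'   `theta = 1` gives the exact pseudo-inverse.
#' @return List of class `"damped_pinv"`: `pinv` (`[d*p x N]`), `lambda`,
#'   `n_retained`, `variance_explained`, `singular_values`.
#' @export
damped_pinv <- function(H, theta = 0.99) {
  if (!all(is.finite(H))) stop("`H` must be finite")
  if (all(H == 0)) stop("`H` is identically zero")
  if (theta <= 0 || theta > 1) stop("`theta` must be in (0, 1]")
  sv <- svd(H)
  s2 <- sv$d^2
  e <- cumsum(s2) / sum(s2)
  k <- which(e >= theta * (1 - 1e-12))[1]
  rnk <- sum(sv$d > max(dim(H)) * .Machine$double.eps * sv$d[1])
  lambda <- if (k < rnk) s2[k + 1L] else 0
  f <- ifelse(sv$d > 0, sv$d / (s2 + lambda), 0)
  structure(list(pinv = sv$v %*% (f * t(sv$u)), lambda = lambda,
                 n_retained = as.integer(k), variance_explained = e[k],
                 singular_values = sv$d),
            class = "damped_pinv")
}

# Self-tuned averaging weight from two segment residual traces. A zero old
# trace with nonzero new trace means the past model suddenly fails (maximal
# tracking); zero on both sides carries no evidence of change (baseline).
tuning_c_from_traces <- function(tr_new, tr_old, b = 0.05) {
  if (tr_old <= 0) return(if (tr_new <= 0) b else 1 - b)
  min(b + abs(tr_new - tr_old) / tr_old, 1 - b)
}

# Residual trace of the instantaneous regularized LS fit at sample t:
# tr(E'E)/(N-1) with E = z_t - H_t (H_t~+ z_t).
ls_residual_trace <- function(cube, t, p, theta) {
  H <- build_lag_matrix(cube, t, p)
  N <- dim(cube)[1]
  z <- matrix(cube[, , t], N, dim(cube)[2])
  E <- if (all(H == 0)) z
       else z - H %*% (damped_pinv(H, theta)$pinv %*% z)
  sum(E^2) / (N - 1)
}

#' Self-tuning memory decay
#'
#' Computes the per-time adaptation constant `c_t` from the proportional
#' change in innovation residuals between two consecutive non-overlapping
#' segments of length the model order: NEW = samples `t-p ... t` and
#' OLD = samples `t-2p ... t-p-1`. The segment statistic is the mean trace of
#' the residual covariance `E'E / (N - 1)` over the segment's samples, and
#' `c_t = min(b + |tr_new - tr_old| / tr_old, 1 - b)`: when a model carried
#' over from the immediate past stops explaining incoming data, `c_t` rises
#' and the filter's memory shortens.
#'
#' Two residual definitions are available. The default, `"innovation"`, uses
#' the filter's one-step prediction residuals `z_s - H_s x_{s-1}` (the
#' measurement innovations), which spike when the underlying coefficients
#' change; it is obtained by running the recursion up to `t`. The
#' alternative, `"ls"`, fits each sample by its own instantaneous regularized
#' least squares, a filter-independent statistic that reacts to changes in
#' signal variance but not directly to coefficient transitions.
#'
#' During warm-up (before every OLD-segment sample has a full lag window,
#' i.e. `t <= 3p`) the baseline value `b` is returned. A degenerate zero OLD
#' trace yields `1 - b` (maximal tracking) when the NEW trace is positive,
#' and `b` when both vanish.
#'
#' @param Y An [mvts()] or 3-d array.
#' @param p Model order.
#' @param t Time index (1-based).
#' @param b Baseline constant in `(0, 0.5)`; clips `c_t` into `[b, 1-b]`.
#' @param theta Variance-retention threshold passed to [damped_pinv()].
#' @param strategy Residual definition for the segment traces (see Details).
#' @return Scalar `c_t` in `[b, 1-b]`.
#' @export
self_tuning_c <- function(Y, p, t, b = 0.05, theta = 0.99,
                          strategy = c("innovation", "ls")) {
  strategy <- match.arg(strategy)
  if (b <= 0 || b >= 0.5) stop("`b` must be in (0, 0.5)")
  cube <- as_cube(Y)
  if (t <= 3 * p) return(b)  # warm-up: OLD segment lacks full lag windows
  if (strategy == "innovation") {
    fit <- stok_filter(cube[, , seq_len(t), drop = FALSE], p = p, b = b,
                       theta = theta)
    return(fit$c_trajectory[t])
  }
  tr_new <- mean(vapply((t - p):t, ls_residual_trace, numeric(1),
                        cube = cube, p = p, theta = theta))
  tr_old <- mean(vapply((t - 2 * p):(t - p - 1L), ls_residual_trace, numeric(1),
                        cube = cube, p = p, theta = theta))
  if (tr_old <= 0 && tr_new > 0)
    warning("zero old-segment residual trace; c_t set to maximal tracking speed",
            call. = FALSE)
  tuning_c_from_traces(tr_new, tr_old, b)
}

#' Self-Tuning Optimized Kalman filter
#'
#' Adaptive tvMVAR estimation without explicit noise-covariance modeling. At
#' each valid time `t` the state is updated as
#' `x_t = (x_{t-1} + c_t * Hpinv_t z_t) / (1 + c_t)`,
#' where `Hpinv_t` is the damped-SVD pseudo-inverse of the lag matrix
#' ([damped_pinv()]) and `c_t` the self-tuned memory decay
#' ([self_tuning_c()]). The update is an exponential moving average of
#' instantaneous regularized least-squares solutions with data weight
#' `c_t / (1 + c_t)`.
#'
#' @param Y An [mvts()] or 3-d array `[N x d x T]`, `N >= 2`.
#' @param p Model order in samples.
#' @param b Baseline constant of the self-tuning rule (default 0.05), giving
#'   `c_t` in `[0.05, 0.95]`.
#' @param theta Variance-retention threshold of the regularization (default
#'   0.99); `theta = 1` disables regularization (exact pseudo-inverse), the
#'   non-regularized ablation variant.
#' @param fixed_c Optional constant in `(0, 1]` overriding the self-tuning
#'   rule (fixed-memory ablation variant).
#' @param tuning Segment-residual strategy for the self-tuning rule; see
#'   [self_tuning_c()].
#' @param x0 Optional initial state `[d*p x d]` (default zero).
#' @return A `"tvmvar"` estimate with time-varying `c_trajectory`, per-time
#'   residual covariance in `innovation_cov`, and the per-time retained
#'   variance fraction in field `variance_explained`.
#' @seealso [kf_filter()]
#' @export
stok_filter <- function(Y, p, b = 0.05, theta = 0.99, fixed_c = NULL,
                        tuning = c("innovation", "ls"), x0 = NULL) {
  tuning <- match.arg(tuning)
  cube <- as_cube(Y)
  if (!all(is.finite(cube))) stop("non-finite values in input")
  if (b <= 0 || b >= 0.5) stop("`b` must be in (0, 0.5)")
  dm <- dim(cube); N <- dm[1]; d <- dm[2]; Tn <- dm[3]
  if (N < 2L) stop("need N >= 2 trials")
  if (Tn <= p) stop("need T > p")
  x <- if (is.null(x0)) matrix(0, d * p, d) else x0
  coef <- array(NA_real_, c(Tn, p, d, d))
  icov <- array(NA_real_, c(Tn, d, d))
  ctraj <- rep(b, Tn)
  varexp <- rep(NA_real_, Tn)
  res_trace <- rep(NA_real_, Tn)  # cached per-sample segment residual traces
  zero_old_seen <- FALSE
  for (t in (p + 1L):Tn) {
    H <- build_lag_matrix(cube, t, p)
    z <- matrix(cube[, , t], N, d)
    if (all(H == 0)) {  # degenerate window (e.g. all-zero input)
      dpv <- list(variance_explained = 1)
      xls <- matrix(0, d * p, d)
    } else {
      dpv <- damped_pinv(H, theta)
      xls <- dpv$pinv %*% z
    }
    res_trace[t] <- if (tuning == "innovation") {
      E_pred <- z - H %*% x  # one-step prediction residual (innovation)
      sum(E_pred^2) / (N - 1)
    } else {
      E_ls <- z - H %*% xls
      sum(E_ls^2) / (N - 1)
    }
    if (!is.null(fixed_c)) {
      ct <- fixed_c
    } else if (t > 3 * p) {
      tr_new <- mean(res_trace[(t - p):t])
      tr_old <- mean(res_trace[(t - 2L * p):(t - p - 1L)])
      if (tr_old <= 0 && tr_new > 0) zero_old_seen <- TRUE
      ct <- tuning_c_from_traces(tr_new, tr_old, b)
    } else {
      ct <- b
    }
    x <- (x + ct * xls) / (1 + ct)
    if (!all(is.finite(x)))
      stop(sprintf("non-finite state at t = %d", t))
    E <- z - H %*% x
    coef[t, , , ] <- state_to_coefficients(x, d, p)
    icov[t, , ] <- crossprod(E) / (N - 1)
    ctraj[t] <- ct
    varexp[t] <- dpv$variance_explained
  }
  if (zero_old_seen)
    warning("zero old-segment residual trace encountered; c_t set to 1 - b there",
            call. = FALSE)
  fs <- if (inherits(Y, "mvts")) Y$fs else NA_real_
  new_tvmvar(coef, as.integer(p), icov, ctraj, fs, "stok",
             extra = list(b = b, theta = theta, tuning = tuning,
                          variance_explained = varexp))
}
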