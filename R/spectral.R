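# Frequency-domain transforms of tvMVAR coefficients.
#
# The coefficient polynomial is evaluated on the unit circle with the
# identity term included, Abar(f, t) = I - sum_k A_{k,t} exp(-i 2 pi f k / fs)
# (the standard PDC / transfer-function convention: at A = 0 the spectrum is
# white and Abar is invertible). Frequencies are in Hz; the normalized
# digital frequency is f / fs.

default_freqs <- function(fs) seq(1, floor(min(100, fs / 2)))

coef_and_fs <- function(estimate) {
  if (!is.list(estimate) || is.null(estimate$coefficients))
    stop("expected a tvMVAR estimate or ground-truth model")
  fs <- estimate$fs
  if (is.null(fs) || !is.finite(fs)) stop("estimate carries no sampling rate")
  list(A = estimate$coefficients, fs = fs)
}

check_freqs <- function(freqs, fs) {
  if (length(freqs) < 1L) stop("empty frequency vector")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (any(freqs > fs / 2 + 1e-9)) stop("frequencies above Nyquist (fs/2)")
  as.numeric(freqs)
}

# Abar(f, t) for a single frequency, vectorized over time:
# complex array [d, d, T]; NA-masked time points propagate NA.
abar_one_freq <- function(A, f, fs) {
  dm <- dim(A)  # [T, p, d, d]
  Tn <- dm[1]; p <- dm[2]; d <- dm[3]
  phase <- exp(-2i * pi * f * seq_len(p) / fs)
  acc <- array(0 + 0i, c(Tn, d, d))
  for (k in seq_len(p))
    acc <- acc + array(A[, k, , , drop = FALSE], c(Tn, d, d)) * phase[k]
  out <- -aperm(acc, c(2, 3, 1))  # [d, d, T]
  for (l in seq_len(d)) out[l, l, ] <- out[l, l, ] + 1
  out
}

#' Frequency representation of tvMVAR coefficients
#'
#' Evaluates `Abar(f, t) = I - sum_k A_{k,t} exp(-i 2 pi f k / fs)` over a
#' frequency grid.
#'
#' @param estimate A `"tvmvar"` estimate (from [kf_filter()] /
#'   [stok_filter()]) or a ground-truth model from the simulator.
#' @param freqs Frequencies in Hz, within `(0, fs/2]`. Default: 1 Hz steps
#'   from 1 to 100 Hz, clipped to Nyquist.
#' @return Complex array `[d x d x F x T]`.
#' @export
ar_spectrum <- function(estimate, freqs = NULL) {
  cf <- coef_and_fs(estimate)
  if (is.null(freqs)) freqs <- default_freqs(cf$fs)
  freqs <- check_freqs(freqs, cf$fs)
  dm <- dim(cf$A); Tn <- dm[1]; d <- dm[3]
  out <- array(NA_complex_, c(d, d, length(freqs), Tn))
  for (i in seq_along(freqs))
    out[, , i, ] <- abar_one_freq(cf$A, freqs[i], cf$fs)
  out
}

new_spectral <- function(values, freqs, fs, kind) {
  structure(list(values = values, freqs = freqs, fs = fs, kind = kind),
            class = "spectral_connectivity")
}

#' @export
print.spectral_connectivity <- function(x, ...) {
  cat(sprintf("<spectral_connectivity> kind = %s, dims [%s], %d freqs (%g-%g Hz)\n",
              x$kind, paste(dim(x$values), collapse = " x "),
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Squared row-normalized partial directed coherence
#'
#' The direct directed influence from channel `j` to channel `l` at frequency
#' `f` and time `t`:
#' `pdc[l, j, f, t] = |Abar_lj(f,t)|^2 / sum_m |Abar_lm(f,t)|^2`.
#' Each target row sums to 1 over sources; values lie in `[0, 1]`.
#'
#' @inheritParams ar_spectrum
#' @return A `"spectral_connectivity"` object with `values` of dimension
#'   `[d x d x F x T]` and `kind = "pdc"`. Time points without a valid
#'   estimate are `NA`.
#' @export
pdc <- function(estimate, freqs = NULL) {
  cf <- coef_and_fs(estimate)
  if (is.null(freqs)) freqs <- default_freqs(cf$fs)
  freqs <- check_freqs(freqs, cf$fs)
  dm <- dim(cf$A); Tn <- dm[1]; p <- dm[2]; d <- dm[3]
  vals <- array(NA_real_, c(d, d, length(freqs), Tn))
  # evaluate the coefficient polynomial at all frequencies with one complex
  # matrix product: rows index (t, l, j), columns index lag k
  CM <- aperm(cf$A, c(1, 3, 4, 2))
  dim(CM) <- c(Tn * d * d, p)
  diag_idx <- as.vector(outer(seq_len(Tn), (seq_len(d) - 1L) * (Tn + Tn * d),
                              "+"))  # (t, l, l) positions in [T, d, d]
  # chunk the frequency axis to bound the complex buffer
  for (blk in split(seq_along(freqs), ceiling(seq_along(freqs) / 16))) {
    phases <- exp(outer(seq_len(p), freqs[blk], function(k, f)
      -2i * pi * f * k / cf$fs))
    ACC <- CM %*% phases  # [T*d*d x length(blk)], Abar = I - this
    for (ii in seq_along(blk)) {
      w <- -ACC[, ii]
      w[diag_idx] <- w[diag_idx] + 1
      p2 <- matrix(Re(w)^2 + Im(w)^2, Tn * d, d)  # columns = source j
      denom <- rowSums(p2)                        # over sources, per (t, l)
      if (any(denom == 0, na.rm = TRUE))
        stop("zero PDC row denominator (degenerate spectrum)")
      vals[, , blk[ii], ] <- aperm(array(p2 / denom, c(Tn, d, d)), c(2, 3, 1))
    }
  }
  new_spectral(vals, freqs, cf$fs, "pdc")
}

# PDC pooled straight to off-diagonal cells, skipping the [d,d,F,T] tensor.
# Cell order is (t, directed pair) within frequency; roc_auc() is invariant
# to cell order as long as ground truth and estimate share it.
pdc_cells_from_coef <- function(A, fs, freqs) {
  dm <- dim(A); Tn <- dm[1]; p <- dm[2]; d <- dm[3]
  off_cols <- which(!diag(d))
  CM <- aperm(A, c(1, 3, 4, 2))
  dim(CM) <- c(Tn * d * d, p)
  CM <- CM + 0i
  diag_idx <- as.vector(outer(seq_len(Tn), (seq_len(d) - 1L) * (Tn + Tn * d),
                              "+"))
  out <- matrix(NA_real_, Tn * length(off_cols), length(freqs))
  for (blk in split(seq_along(freqs), ceiling(seq_along(freqs) / 16))) {
    phases <- exp(outer(seq_len(p), freqs[blk], function(k, f)
      -2i * pi * f * k / fs))
    ACC <- CM %*% phases
    for (ii in seq_along(blk)) {
      w <- -ACC[, ii]
      w[diag_idx] <- w[diag_idx] + 1
      p2 <- matrix(Re(w)^2 + Im(w)^2, Tn * d, d)
      p2 <- p2 / rowSums(p2)
      dim(p2) <- c(Tn, d * d)
      out[, blk[ii]] <- p2[, off_cols]
    }
  }
  dim(out) <- NULL
  out
}

# `t_range` restricts the pooled cells to a time subset (e.g. the valid
# filter range), so downstream scoring never sees NA warm-up rows.
pdc_cells <- function(estimate, freqs = NULL, t_range = NULL) {
  cf <- coef_and_fs(estimate)
  if (is.null(freqs)) freqs <- default_freqs(cf$fs)
  freqs <- check_freqs(freqs, cf$fs)
  A <- if (is.null(t_range)) cf$A else cf$A[t_range, , , , drop = FALSE]
  pdc_cells_from_coef(A, cf$fs, freqs)
}

# Ground-truth cells exploiting piecewise-constant regimes: PDC is computed
# once per regime and replicated over the regime's samples.
ground_truth_pdc_cells <- function(model, freqs = NULL, t_range = NULL) {
  if (is.null(freqs)) freqs <- default_freqs(model$fs)
  freqs <- check_freqs(freqs, model$fs)
  dm <- dim(model$coefficients); Tn <- dm[1]; d <- dm[3]
  if (is.null(t_range)) t_range <- seq_len(Tn)
  bounds <- model$regime_bounds
  R <- length(bounds)
  Asmall <- model$coefficients[bounds, , , , drop = FALSE]
  small <- pdc_cells_from_coef(Asmall, model$fs, freqs)  # (r, pair) within f
  reg_of_t <- findInterval(t_range, bounds)
  Joff <- d * d - d
  sm <- array(small, c(R, Joff * length(freqs)))
  as.numeric(sm[reg_of_t, ])
}

#' Innovation covariance summary for spectral estimation
#'
#' The innovation covariance entering the parametric PSD is taken as the
#' element-wise median of the per-time innovation covariance over the last
#' half of the valid samples (discarding the initial adaptation stage of the
#' filter), symmetrized.
#'
#' @param estimate A `"tvmvar"` estimate.
#' @return Symmetric matrix `[d x d]`.
#' @export
innovation_covariance <- function(estimate) {
  ic <- estimate$innovation_cov
  valid <- which(apply(is.finite(ic), 1, all))
  if (length(valid) < 4L) stop("need at least 4 valid time points")
  n <- length(valid)
  last <- valid[(floor(n / 2) + 1L):n]
  S <- apply(ic[last, , , drop = FALSE], c(2, 3), stats::median)
  (S + t(S)) / 2
}

#' Parametric time-varying power spectral density
#'
#' Computes `PSD(f, t) = B(f,t) Sigma B(f,t)^*` with transfer function
#' `B = Abar^{-1}` and `Sigma` the innovation covariance
#' ([innovation_covariance()] by default). Returns the per-channel (diagonal)
#' real spectra; set `full = TRUE` for the full complex cross-spectral
#' matrices.
#'
#' @inheritParams ar_spectrum
#' @param sigma Optional `[d x d]` innovation covariance; default is
#'   [innovation_covariance()] of the estimate.
#' @param full If `TRUE`, return the complex array `[d x d x F x T]` instead
#'   of a `"spectral_connectivity"`.
#' @return A `"spectral_connectivity"` with `values` `[d x F x T]` (kind
#'   `"psd"`), or the full complex array when `full = TRUE`. Time-frequency
#'   points with a singular `Abar` are `NaN` (with a warning).
#' @export
psd <- function(estimate, freqs = NULL, sigma = NULL, full = FALSE) {
  cf <- coef_and_fs(estimate)
  if (is.null(freqs)) freqs <- default_freqs(cf$fs)
  freqs <- check_freqs(freqs, cf$fs)
  if (is.null(sigma)) sigma <- innovation_covariance(estimate)
  dm <- dim(cf$A); Tn <- dm[1]; d <- dm[3]
  valid <- which(apply(is.finite(cf$A), 1, all))
  Fq <- length(freqs)
  outfull <- if (full) array(NA_complex_, c(d, d, Fq, Tn)) else NULL
  vals <- array(NA_real_, c(d, Fq, Tn))
  n_singular <- 0L
  for (i in seq_len(Fq)) {
    ab <- abar_one_freq(cf$A, freqs[i], cf$fs)
    for (t in valid) {
      B <- tryCatch(solve(ab[, , t]), error = function(e) NULL)
      if (is.null(B)) {
        n_singular <- n_singular + 1L
        vals[, i, t] <- NaN
        if (full) outfull[, , i, t] <- NaN
        next
      }
      S <- B %*% sigma %*% Conj(t(B))
      vals[, i, t] <- Re(diag(S))
      if (full) outfull[, , i, t] <- S
    }
  }
  if (n_singular > 0L)
    warning(sprintf("singular Abar at %d (f, t) points; PSD set to NaN", n_singular),
            call. = FALSE)
  if (full) outfull else new_spectral(vals, freqs, cf$fs, "psd")
}
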