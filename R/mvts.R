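#' Multi-trial time series
#'
#' Container for a set of temporally aligned realizations (trials) of the same
#' multivariate stochastic process, e.g. epoched multi-channel EEG. The data
#' cube is indexed trials x channels x time and carries its sampling rate so
#' downstream frequency-domain measures can work in Hz.
#'
#' @param data Numeric array `[N trials x d channels x T samples]`, all finite.
#' @param fs Sampling rate in Hz.
#' @param channels Optional character vector of channel labels (length `d`).
#' @param time Optional numeric vector of sample times in seconds (length `T`,
#'   strictly increasing with step `1/fs`; may start negative for pre-stimulus
#'   baselines). Defaults to `0, 1/fs, 2/fs, ...`.
#'
#' @return An object of class `"mvts"`: a list with elements `data`, `fs`,
#'   `channels`, `time`.
#' @examples
#' y <- mvts(array(rnorm(4 * 2 * 50), c(4, 2, 50)), fs = 200)
#' dim(y$data)
#' @export
mvts <- function(data, fs, channels = NULL, time = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials x channels x time]")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("`data` must be finite")
  dm <- dim(data)
  if (dm[1] < 1L || dm[2] < 2L || dm[3] < 2L)
    stop("need N >= 1 trials, d >= 2 channels, T >= 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dm[2]))
  if (length(channels) != dm[2]) stop("`channels` must have one label per channel")
  if (is.null(time)) time <- seq(0, by = 1 / fs, length.out = dm[3])
  if (length(time) != dm[3]) stop("`time` must have length T")
  if (any(diff(time) <= 0) || max(abs(diff(time) - 1 / fs)) > 1e-6 / fs)
    stop("`time` must be strictly increasing with step 1/fs")
  structure(list(data = data, fs = fs, channels = as.character(channels),
                 time = as.numeric(time)),
            class = "mvts")
}

#' @export
print.mvts <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<mvts> %d trials x %d channels x %d samples @ %g Hz\n",
              dm[1], dm[2], dm[3], x$fs))
  cat(sprintf("  time: [%.4f, %.4f] s\n", x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' @export
dim.mvts <- function(x) dim(x$data)

#' Read a single-trial time series from CSV
#'
#' Convenience reader for toy data: one column per channel, one row per time
#' sample. The result is an [mvts()] with a single trial.
#'
#' @param path Path to a CSV file with a header row of channel names.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An [mvts()] with `N = 1`.
#' @export
read_mvts_csv <- function(path, fs, t0 = 0) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("CSV must contain numeric columns only")
  dat <- array(0, c(1L, ncol(m), nrow(m)))
  dat[1L, , ] <- t(m)
  mvts(dat, fs = fs, channels = colnames(m),
       time = seq(t0, by = 1 / fs, length.out = nrow(m)))
}

# Coerce an mvts or bare 3-d array to the data cube, with dims.
as_cube <- function(Y) {
  if (inherits(Y, "mvts")) Y$data
  else if (is.array(Y) && length(dim(Y)) == 3L) Y
  else stop("expected an `mvts` or a 3-d array [trials x channels x time]")
}

#' Time-varying MVAR estimate
#'
#' Internal constructor for the result of [kf_filter()] and [stok_filter()]:
#' the full time sequence of AR coefficient matrices, per-time innovation
#' covariance, and the adaptation-constant trajectory.
#'
#' @param coefficients `[T x p x d x d]` array; entry `[t, k, l, j]` is the
#'   influence of channel `j` at lag `k` on channel `l` at time `t`.
#' @param order Model order `p` in samples.
#' @param innovation_cov `[T x d x d]` array of per-time innovation covariance.
#' @param c_trajectory Length-`T` vector of adaptation constants.
#' @param fs Sampling rate (Hz).
#' @param method Label of the producing filter.
#' @param extra Named list of method-specific fields appended to the object.
#' @return Object of class `"tvmvar"`. The first `p` samples have no full lag
#'   window and are NaN-masked; `valid_from` marks the first valid time index
#'   (1-based, equal to `p + 1`).
#' @keywords internal
new_tvmvar <- function(coefficients, order, innovation_cov, c_trajectory, fs,
                       method, extra = list()) {
  out <- c(list(coefficients = coefficients, order = order,
                innovation_cov = innovation_cov,
                c_trajectory = c_trajectory, fs = fs,
                valid_from = order + 1L, method = method),
           extra)
  class(out) <- "tvmvar"
  out
}

#' @export
print.tvmvar <- function(x, ...) {
  dm <- dim(x$coefficients)
  cat(sprintf("<tvmvar> %s estimate: T = %d, p = %d, d = %d (valid from t = %d)\n",
              x$method, dm[1], dm[2], dm[3], x$valid_from))
  cr <- range(x$c_trajectory, na.rm = TRUE)
  cat(sprintf("  c in [%.4g, %.4g]\n", cr[1], cr[2]))
  invisible(x)
}
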