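# Shared fixture builders (all data generated in code).

# Deterministic fill Y[n, c, t] = 100 n + 10 c + t for index-arithmetic oracles.
fill_cube <- function(N, d, Tn) {
  Y <- array(0, c(N, d, Tn))
  for (n in seq_len(N)) for (ch in seq_len(d)) for (t in seq_len(Tn))
    Y[n, ch, t] <- 100 * n + 10 * ch + t
  Y
}

# Stationary MVAR sample cube from a fixed coefficient block [p x d x d].
ar_cube <- function(A, N, Tn, burn = 30L, innov_sd = 1) {
  p <- dim(A)[1]; d <- dim(A)[2]
  Y <- array(0, c(N, d, Tn + burn))
  for (t in seq_len(Tn + burn)) {
    acc <- matrix(stats::rnorm(N * d, sd = innov_sd), N, d)
    for (k in seq_len(min(p, t - 1L)))
      acc <- acc + Y[, , t - k] %*% t(A[k, , ])
    Y[, , t] <- acc
  }
  Y[, , (burn + 1L):(Tn + burn), drop = FALSE]
}

# Pooled multi-trial OLS estimate of a stationary MVAR (oracle for the
# late-time behaviour of the adaptive filters).
pooled_ols <- function(cube, p, tt = NULL) {
  dm <- dim(cube); N <- dm[1]; d <- dm[2]; Tn <- dm[3]
  if (is.null(tt)) tt <- (p + 1L):Tn
  H <- do.call(rbind, lapply(tt, function(t) build_lag_matrix(cube, t, p)))
  Z <- do.call(rbind, lapply(tt, function(t) matrix(cube[, , t], N, d)))
  x <- qr.solve(H, Z)
  state_to_coefficients(x, d, p)
}

# The full-size two-node demo is used by several files; build it once.
demo_cache <- new.env()
get_demo <- function() {
  if (is.null(demo_cache$demo))
    demo_cache$demo <- bivariate_demo(seed = 42)
  demo_cache$demo
}
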