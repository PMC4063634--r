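# Small numerical helpers shared across modules.

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# subdivide each grid interval into k equal parts (keeps original nodes at
# positions 1, 1+k, 1+2k, ...)
refine_grid <- function(x, k) {
  n <- length(x)
  out <- numeric((n - 1) * k + 1)
  for (j in seq_len(k)) {
    w <- (j - 1) / k
    out[seq(j, by = k, length.out = n - 1)] <-
      x[-n] * (1 - w) + x[-1] * w
  }
  out[(n - 1) * k + 1] <- x[n]
  out
}

# normalize exp(logd) to a unit-integral density over x, in the log domain
normalize_log_density <- function(x, logd) {
  m <- max(logd)
  if (!is.finite(m)) stop("non-normalizable density (overflow in exponent)")
  d <- exp(logd - m)
  Z <- trapz(x, d)
  if (!is.finite(Z) || Z <= 0) stop("non-normalizable density")
  d / Z
}
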