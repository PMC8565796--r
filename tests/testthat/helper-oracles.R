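# Independent brute-force oracles, kept deliberately naive (scalar loops,
# textbook formulas) so they cannot share code paths with the package.

# pooled two-sample t for two scalar samples
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Benjamini-Hochberg step-up, literal definition
oracle_bh_stepup <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  sig <- rep(FALSE, m)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  sig
}

# half-maximum width of a 1D profile, linear interpolation between samples
oracle_profile_fwhm <- function(y) {
  half <- max(y) / 2
  i_max <- which.max(y)
  right <- NA_real_
  for (i in (i_max + 1L):length(y)) {
    if (y[i] < half) {
      right <- (i - 1L) + (y[i - 1L] - half) / (y[i - 1L] - y[i])
      break
    }
  }
  left <- NA_real_
  for (i in (i_max - 1L):1L) {
    if (y[i] < half) {
      left <- (i + 1L) - (y[i + 1L] - half) / (y[i + 1L] - y[i])
      break
    }
  }
  right - left
}
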