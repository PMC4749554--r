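# Shared fixture builders (everything is generated in code; no binary files).

# A blank frame with a filled rectangle of a given label.
rect_frame <- function(dim = c(20, 20), rows, cols, label = 1L, base = NULL) {
  f <- if (is.null(base)) matrix(0L, dim[1], dim[2]) else base
  f[rows, cols] <- as.integer(label)
  f
}

# Random blobby mask pair for set-difference oracles.
random_mask <- function(dim = c(12, 12), p = 0.4) {
  matrix(runif(prod(dim)) < p, dim[1], dim[2])
}

# Brute-force MSD over all in-window pairs (independent of .msd_window).
bf_msd <- function(x, y, k) {
  i <- seq_len(length(x) - k)
  mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
}

# Brute-force normalized cross-covariance at one lag, sign convention:
# value at lag l correlates p(t) with r(t - l).
bf_xcov <- function(p, r, l) {
  pd <- p - mean(p); rd <- r - mean(r)
  t <- seq_along(p)
  ok <- t + l >= 1 & t + l <= length(p)
  sum(pd[t[ok] + l] * rd[t[ok]]) / sqrt(sum(pd^2) * sum(rd^2))
}
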