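# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementation.

# Brute-force trough/prominence oracle. Plateaus are found via rle();
# barriers are located with vectorized which()/max() scans: for each side,
# find the nearest strictly deeper sample, take the max over the stretch
# before it (or the whole side if none). A candidate survives if
# min(barriers) - value >= threshold_ratio * range.
oracle_troughs <- function(x, threshold_ratio = 0.05) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (n < 3 || rng <= 0) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  events <- integer(0)
  for (k in seq_len(m)) {
    if (k == 1L || k == m) next
    v <- r$values[k]
    if (v >= r$values[k - 1] || v >= r$values[k + 1]) next
    i0 <- starts[k]; j0 <- ends[k]
    left <- x[seq_len(i0 - 1L)]
    deeper <- which(left < v)
    barL <- if (length(deeper)) max(left[(max(deeper) + 1L):(i0 - 1L)])
            else max(left)
    right <- x[(j0 + 1L):n]
    deeper_r <- which(right < v)
    barR <- if (length(deeper_r)) max(right[seq_len(min(deeper_r) - 1L)])
            else max(right)
    if (min(barL, barR) - v >= threshold_ratio * rng) {
      events <- c(events, (i0 + j0) %/% 2L)
    }
  }
  events
}

# Direct time-domain complex-Morlet convolution (O(n * L) double loop over
# window positions), zero boundary. Same analytic formula, entirely
# different computation path from the FFT implementation.
oracle_morlet_power <- function(x, scale, center_frequency = 1,
                                bandwidth = 2, trunc_sd = 4) {
  L <- ceiling(trunc_sd * sqrt(bandwidth / 2) * scale)
  k <- seq(-L, L)
  psi <- (pi * bandwidth)^(-0.5) *
    exp(2i * pi * center_frequency * k / scale) *
    exp(-(k / scale)^2 / bandwidth) / sqrt(scale)
  n <- length(x)
  xp <- c(rep(0, L), x, rep(0, L))
  vapply(seq_len(n), function(t) {
    Mod(sum(xp[t:(t + 2 * L)] * rev(psi)))^2
  }, numeric(1))
}

# Random series for detector tests: alternating white noise and random walks.
random_series <- function(len, i) {
  if (i %% 2 == 0) cumsum(stats::rnorm(len)) else stats::rnorm(len)
}

# Paired two-condition PLS dataset with a known within-subject effect:
# X[s, c, e] = subject baseline + delta * 1(c = 2, e affected) + N(0, sd^2).
# Rows stacked by condition block, as pls_dataset() expects.
make_effect_dataset <- function(n_subjects, n_elements, affected = integer(0),
                                delta = 0, sd_within = 1, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n_subjects * n_elements, mean = 10, sd = 2),
                 n_subjects, n_elements)
  X1 <- base + matrix(rnorm(n_subjects * n_elements, sd = sd_within),
                      n_subjects, n_elements)
  X2 <- base + matrix(rnorm(n_subjects * n_elements, sd = sd_within),
                      n_subjects, n_elements)
  if (length(affected)) X2[, affected] <- X2[, affected] + delta
  pls_dataset(rbind(X1, X2), n_subjects = n_subjects, n_conditions = 2)
}
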