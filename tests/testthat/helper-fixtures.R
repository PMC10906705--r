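# Fixture builders and independent oracles shared across test files.

# frame with given per-channel counts matrix (rows = intervals)
make_frame <- function(counts, period = 7) {
  counts <- as.matrix(counts)
  particle_frame(time_s = (seq_len(nrow(counts)) - 1) * period,
                 counts = counts, sample_period_s = period)
}

# aggregate series with prescribed per-interval aerosol/droplet totals:
# aerosol counts go to the first channel, droplet counts to the fifth
make_series <- function(aerosol, droplet = rep(0, length(aerosol)),
                        period = 7) {
  counts <- matrix(0, nrow = length(aerosol), ncol = 6)
  counts[, 1] <- aerosol
  counts[, 5] <- droplet
  aggregate_size_fractions(make_frame(counts, period = period))
}

# brute-force sliding median with shrinking edge windows (oracle)
naive_running_median <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# closed-form Welch t-test (oracle)
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

# full hypergeometric enumeration of the two-sided exact test (oracle)
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  obs <- probs[k == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small study config used by pipeline tests (cheap but complete)
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_egd = 4, n_cytosponge = 4, seed = seed, ...)
}
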