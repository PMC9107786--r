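# Small hand-constructed communities used across test files.

# step curve: value `hi` on [from, to] (inclusive grid indices), else `lo`
step_curve <- function(n, from, to, hi = 1, lo = 0) {
  v <- rep(lo, n)
  v[from:to] <- hi
  v
}

# a set of S <= 4 step-curve communities on a common grid, spanning
# identical / nested / disjoint / partially overlapping configurations
fixture_communities <- function() {
  n <- 41
  tg <- 0:(n - 1)
  mk <- function(...) {
    m <- cbind(...)
    colnames(m) <- paste0("sp", seq_len(ncol(m)))
    phenology_community(tg, m, stage = "smoothed")
  }
  list(
    disjoint2   = mk(step_curve(n, 1, 15), step_curve(n, 25, 40)),
    constants2  = mk(rep(1, n), rep(3, n)),
    partial2    = mk(step_curve(n, 1, 25), step_curve(n, 15, 40)),
    nested3     = mk(step_curve(n, 5, 35), step_curve(n, 10, 30, hi = 2),
                     step_curve(n, 15, 25, hi = 4)),
    mixed4      = mk(step_curve(n, 1, 10), step_curve(n, 8, 20, hi = 2),
                     step_curve(n, 18, 30, hi = 0.5), step_curve(n, 28, 40)),
    identical3  = mk(step_curve(n, 10, 30), step_curve(n, 10, 30),
                     step_curve(n, 10, 30))
  )
}

# write a community to a temp CSV in long layout
write_long_csv <- function(comm, path) {
  df <- data.frame(
    time = rep(comm$times, times = length(comm$species)),
    species = rep(comm$species, each = length(comm$times)),
    value = as.vector(comm$intensity)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# phenology-like noisy pulse series for wavelet tests
pulse_series <- function(n = 120, seed = 1) {
  set.seed(seed)
  t <- 0:(n - 1)
  5 * exp(-((t - 0.3 * n) / (n / 15))^2) +
    3 * exp(-((t - 0.75 * n) / (n / 20))^2) +
    abs(rnorm(n, 0, 0.3)) + 1
}
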