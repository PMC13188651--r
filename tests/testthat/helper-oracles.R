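# brute-force Kendall tau-b over all pairs, independent of stats::cor
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  P <- 0L; Q <- 0L; tx <- 0L; ty <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0) tx <- tx + 1L
      if (dy == 0) ty <- ty + 1L
      if (dx * dy > 0) P <- P + 1L
      if (dx * dy < 0) Q <- Q + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  (P - Q) / sqrt((n0 - tx) * (n0 - ty))
}

# random integer-valued vectors guaranteed to contain ties and variation
random_tied_vector <- function(n, k = 5) {
  repeat {
    v <- sample.int(k, n, replace = TRUE)
    if (length(unique(v)) > 1) return(v)
  }
}

study_cohort <- function(seed = 1) generate_cohort(generator_config(seed = seed))
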