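# Shared fixtures, built in code at test time.

# compact schedule for fast end-to-end tests (blocks still >= 120 s so
# spectral features stay defined)
short_schedule <- function(n = 3, block_s = 150) {
  cond <- rep(c("fixation", "pleasant", "unpleasant"), length.out = n)
  data.frame(label = paste0("B", seq_len(n)), condition = cond,
             start_s = (seq_len(n) - 1) * block_s, duration_s = block_s,
             stringsAsFactors = FALSE)
}

# metronome-regular R-peak series
regular_peaks <- function(rr_ms = 1000, n = 61, amp = 1, t0 = 0) {
  rpeak_series(t0 + (seq_len(n) - 1) * rr_ms, "detected", amp)
}

# device presets are noise/offset/artifact-free unless overridden, so the
# "quiet" aliases just document intent at call sites
quiet_brainamp <- function(...) device_brainamp(...)
quiet_bitalino <- function(...) device_bitalino(...)

# independent ICC(2,1) oracle: explicit sums of squares, scalar loops only
icc_oracle_sums <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + (sum(x[i, ]) / k - gm)^2
  ssr <- ssr * k
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + (sum(x[, j]) / n - gm)^2
  ssc <- ssc * n
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (x[i, j] - sum(x[i, ]) / k - sum(x[, j]) / n + gm)^2
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# independent repeated-measures SD-of-differences oracle via aov
ba_oracle_sd <- function(d, participant) {
  g <- factor(participant)
  a <- stats::anova(stats::lm(d ~ g))
  msb <- a[1, "Mean Sq"]; msw <- a[2, "Mean Sq"]
  m_i <- tabulate(g); n <- length(d); I <- nlevels(g)
  m0 <- (n - sum(m_i^2) / n) / (I - 1)
  sqrt(max(0, (msb - msw) / m0) + msw)
}

# amplitude of the f-Hz component of a uniformly sampled signal
tone_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  2 * abs(mean(x * exp(-2i * pi * f * t)))
}
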