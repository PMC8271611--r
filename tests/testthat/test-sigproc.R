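test_that("band-pass blocks DC and is transparent in the passband", {
  fs <- 1000
  dc <- ecg_signal(rep(1, 20 * fs), fs)
  y <- bandpass_filter(dc, 1, 40, 3)$samples
  expect_lt(max(abs(y[(5 * fs):(15 * fs)])), 1e-3)

  tt <- (0:(60 * fs - 1)) / fs
  tone <- ecg_signal(sin(2 * pi * 10 * tt), fs)
  y10 <- bandpass_filter(tone, 1, 40, 3)$samples
  sel <- (10 * fs):(50 * fs)
  expect_lt(abs(tone_amplitude(y10[sel], 10, fs) - 1), 0.02)
})

test_that("stop-band attenuation matches the squared analytic Butterworth response", {
  # forward-backward filtering squares the one-pass |H(f)|
  fs <- 1000
  tt <- (0:(200 * fs - 1)) / fs
  x <- ecg_signal(sin(2 * pi * 0.1 * tt), fs)
  y <- bandpass_filter(x, 1, 40, 3)$samples
  sel <- (50 * fs):(150 * fs)
  h1 <- (0.1 / 1)^3 / sqrt(1 + (0.1 / 1)^6)  # 3rd-order high-pass at 0.1 Hz
  expect_lt(abs(tone_amplitude(y[sel], 0.1, fs) - h1^2) / h1^2, 0.05)
})

test_that("too-short signals are rejected before filtering", {
  expect_error(bandpass_filter(ecg_signal(rnorm(1000), 1000), 1, 40),
               "settling")
})

test_that("artifact flagging is silent on clean recordings and localises bursts", {
  p <- rr_process_params(jitter_sd = 2)
  g <- generate_rr_process(p, 120, seed = 21)
  clean <- bandpass_filter(apply_device_model(render_ecg(g$rr),
                                              quiet_bitalino(noise_snr = 20),
                                              seed = 3))
  expect_equal(nrow(flag_artifacts(clean)), 0)

  x <- clean
  i0 <- 50 * 1000 + 1  # 1-s burst at t = 50 s, 10x the R amplitude
  k <- seq_len(1000)
  x$samples[i0 + k - 1] <- x$samples[i0 + k - 1] +
    10 * sin(pi * k / 1000) * sin(2 * pi * 4 * k / 1000)
  mask <- flag_artifacts(x)
  expect_equal(nrow(mask), 1)
  expect_lt(mask$start_ms, 51000)
  expect_gt(mask$end_ms, 50000)
})

test_that("nearby bursts merge into a single artifact window", {
  p <- rr_process_params(jitter_sd = 2)
  g <- generate_rr_process(p, 120, seed = 22)
  x <- bandpass_filter(apply_device_model(render_ecg(g$rr), quiet_bitalino()))
  for (s in c(50.0, 50.5)) {  # two 0.3-s bursts 0.2 s apart
    k <- seq_len(300)
    idx <- round(s * 1000) + k
    x$samples[idx] <- x$samples[idx] + 10 * sin(pi * k / 300)
  }
  mask <- flag_artifacts(x)
  expect_equal(nrow(mask), 1)
})

test_that("constant signals yield an empty mask with a warning", {
  expect_warning(m <- flag_artifacts(ecg_signal(rep(0, 20000), 1000)),
                 "constant")
  expect_equal(nrow(m), 0)
})

test_that("artifact interpolation leaves unflagged samples bit-identical and is exact on ramps", {
  x <- ecg_signal(seq(0, 10, length.out = 10001), 1000)
  mask <- data.frame(start_ms = 4000, end_ms = 5000)
  y <- interpolate_artifacts(x, mask)
  expect_equal(y$samples, x$samples, tolerance = 1e-10)  # cubic through linear
  out <- sample_times(x) < 4000 | sample_times(x) > 5000
  expect_identical(y$samples[out], x$samples[out])
  expect_identical(interpolate_artifacts(x, NULL)$samples, x$samples)
  big <- data.frame(start_ms = 0, end_ms = 6000)
  expect_error(interpolate_artifacts(x, big), "block unusable")
})

test_that("a beat lost to artifact interpolation is re-inserted near its true time", {
  p <- rr_process_params(jitter_sd = 2)
  g <- generate_rr_process(p, 180, seed = 23)
  filt <- bandpass_filter(apply_device_model(render_ecg(g$rr),
                                             quiet_bitalino(noise_snr = 25),
                                             seed = 7))
  target <- g$rr$onsets[which.min(abs(g$rr$onsets - 90000))]
  k <- seq_len(1000)
  idx <- round(target - 500) + k
  filt$samples[idx] <- filt$samples[idx] +
    10 * sin(pi * k / 1000) * sin(2 * pi * 4 * k / 1000)
  mask <- flag_artifacts(filt)
  expect_gte(nrow(mask), 1)
  cleaned <- interpolate_artifacts(filt, mask)
  pk <- correct_beats(detect_r_peaks(cleaned))
  ins <- pk$times[pk$flags == "interpolated"]
  expect_gte(length(ins), 1)
  expect_lte(min(abs(ins - target)), 50)
})

test_that("peak detection recovers a clean rhythm at the right rate", {
  rr <- rr_series((0:59) * 1000, rep(1000, 60))
  pk <- detect_r_peaks(bandpass_filter(render_ecg(rr)))
  expect_gte(length(pk$times), 59)
  expect_lte(length(pk$times), 61)
  d <- diff(pk$times)
  expect_true(all(abs(d[2:(length(d) - 1)] - 1000) <= 2))  # interior beats
  expect_true(all(pk$flags == "detected"))
  expect_error(detect_r_peaks(ecg_signal(rnorm(5000), 1000)), "10 s")
})

test_that("the 480 ms refractory rule rejects T-wave-scale bumps after each R", {
  rr <- rr_series((0:59) * 1000, rep(1000, 60))
  ecg <- render_ecg(rr)
  tm <- sample_times(ecg)
  for (b in (0:59) * 1000 + 300) {  # large spurious bump 300 ms after each R
    sel <- which(abs(tm - b) < 50)
    ecg$samples[sel] <- ecg$samples[sel] + 0.7 * exp(-((tm[sel] - b)^2) / (2 * 11^2))
  }
  pk <- detect_r_peaks(bandpass_filter(ecg))
  expect_lte(length(pk$times), 61)
  expect_true(all(diff(pk$times) >= 480))
  # away from the clipped edge beats, the survivors are the true R peaks,
  # not the bumps
  inner <- pk$times[pk$times > 500 & pk$times < 59500]
  expect_true(all(vapply(inner, function(t)
    min(abs((1:59) * 1000 - t)), numeric(1)) <= 10))
})

test_that("noisy detection still matches true beats within 20 ms", {
  p <- rr_process_params()
  g <- generate_rr_process(p, 300, seed = 31)
  noisy <- apply_device_model(render_ecg(g$rr),
                              quiet_bitalino(noise_snr = 10), seed = 32)
  pk <- detect_r_peaks(bandpass_filter(noisy))
  err <- vapply(pk$times, function(t) min(abs(g$rr$onsets - t)), numeric(1))
  expect_gte(mean(err <= 20), 0.99)
})

test_that("missing beats are filled at the mean of the five preceding intervals", {
  # preceding intervals [820, 800, 810, 790, 780], then a 1600 ms gap:
  # the 5-interval mean is 800, so exactly one peak lands 800 ms after the
  # last good peak
  t <- cumsum(c(0, 820, 800, 810, 790, 780, 1600))
  pk <- rpeak_series(t, "detected", 1)
  out <- correct_beats(pk)
  ins <- out$times[out$flags == "interpolated"]
  expect_equal(ins, t[6] + 800)
  expect_true(all(diff(out$times) >= 480 & diff(out$times) <= 1500))
})

test_that("beat correction is identity on clean series and idempotent", {
  pk <- regular_peaks(820, 100)
  out <- correct_beats(pk)
  expect_identical(out$times, pk$times)
  expect_identical(sum(out$flags == "interpolated"), 0L)

  # idempotency on a series that does need correction
  set.seed(44)
  t <- cumsum(c(0, rnorm(99, 820, 15)))
  t <- t[-sample(10:90, 5)]
  once <- correct_beats(rpeak_series(t, "detected", 1))
  twice <- correct_beats(once)
  expect_equal(twice$times, once$times)
  expect_identical(twice$flags, once$flags)
})

test_that("false peaks drop the candidate with smaller amplitude support", {
  t <- c((0:9) * 1000, 5200)  # spurious small peak 200 ms after beat 5
  o <- order(t)
  pk <- rpeak_series(t[o], "detected", c(rep(1, 10), 0.3)[o])
  out <- correct_beats(pk)
  expect_identical(out$times, (0:9) * 1000)
})

test_that("alignment recovers constant offsets exactly and is linear in the shift", {
  pk_a <- regular_peaks(820, 80)
  res0 <- align_streams(pk_a, pk_a)
  expect_equal(res0$alignment$offset_ms, 0)
  expect_equal(res0$peaks_b$times, pk_a$times)

  for (delta in c(-100, -57, -3.5, 12, 25, 99)) {
    pk_b <- rpeak_series(pk_a$times + delta, "detected", 1)
    res <- align_streams(pk_a, pk_b)
    expect_equal(res$alignment$offset_ms, delta)
    expect_equal(max(abs(res$peaks_b$times - pk_a$times)), 0)
  }
})

test_that("disjoint streams are reported as not concurrent", {
  pk_a <- regular_peaks(820, 40)
  pk_b <- regular_peaks(820, 40, t0 = 400)  # ~half the peaks out of window
  expect_error(align_streams(pk_a, rpeak_series(pk_a$times + 500)),
               "not concurrent")
  expect_error(align_streams(regular_peaks(1000, 5), regular_peaks(1000, 5)),
               "at least 10 peaks")
})
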