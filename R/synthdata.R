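# Synthetic paired-device ECG generator.
#
# The RR process is a mean interval plus two fixed-frequency sinusoids
# (0.1 Hz -> LF band, 0.25 Hz -> HF band) plus white beat-to-beat jitter.
# This model is deliberately simple: every downstream feature (HR, RMSSD,
# LF, HF, LF/HF) has a closed-form ground truth, so the full processing
# chain can be tested by parameter recovery.

#' Parameters of the synthetic RR-interval process
#'
#' Population-level description of the simulated heart rhythm. The RR series
#' of one participant/block is
#' `RR(t) = mean_rr + lf_amp*sin(2*pi*0.1*t) + hf_amp*sin(2*pi*0.25*t) + e`,
#' with `e ~ N(0, jitter_sd^2)` white per beat, each interval evaluated at
#' its own onset time.
#'
#' Defaults emulate the descriptive statistics of a seated picture-viewing
#' session: mean HR about 73 bpm with a 10 bpm between-subject SD, RMSSD
#' about 44 ms and LF/HF about 3 at that heart rate.
#'
#' @param hr_mean population mean heart rate, beats/min; must lie in (40, 125).
#' @param hr_between_subject_sd between-subject SD of mean HR, beats/min.
#' @param lf_amp amplitude of the 0.1 Hz RR modulation, ms.
#' @param hf_amp amplitude of the 0.25 Hz RR modulation, ms.
#' @param jitter_sd SD of white beat-to-beat RR noise, ms.
#' @param amp_sdlog SD (log scale) of per-participant log-normal scaling of
#'   `lf_amp` and `hf_amp` (drawn independently, mean 1); creates the
#'   between-subject dispersion of RMSSD, LF, HF and LF/HF that agreement
#'   statistics require.
#' @param block_hr_sd within-participant block-to-block SD of mean HR,
#'   beats/min.
#' @param seed optional integer seed used by generators when no explicit
#'   seed is given.
#' @return A list of class `rr_process_params`.
#' @export
rr_process_params <- function(hr_mean = 73.065, hr_between_subject_sd = 10.190,
                              lf_amp = 72, hf_amp = 41, jitter_sd = 3,
                              amp_sdlog = 0.4, block_hr_sd = 1, seed = NULL) {
  if (hr_mean <= 40 || hr_mean >= 125)
    stop("hr_mean must lie in (40, 125) beats/min")
  if (lf_amp < 0 || hf_amp < 0 || jitter_sd < 0)
    stop("modulation amplitudes and jitter_sd must be non-negative")
  structure(list(hr_mean = hr_mean,
                 hr_between_subject_sd = hr_between_subject_sd,
                 lf_amp = lf_amp, hf_amp = hf_amp, jitter_sd = jitter_sd,
                 amp_sdlog = amp_sdlog, block_hr_sd = block_hr_sd,
                 seed = seed),
            class = "rr_process_params")
}

#' Device acquisition model
#'
#' Describes one recording channel: its analog band, sampling rate,
#' measurement noise, constant clock offset against the reference clock, and
#' the rate of motion-artifact bursts.
#'
#' @param name device label.
#' @param hp_cutoff high-pass cutoff, Hz (0 disables).
#' @param lp_cutoff low-pass cutoff, Hz.
#' @param sampling_rate sampling rate, Hz.
#' @param noise_snr white measurement noise level as SNR in dB relative to
#'   the RMS of the filtered waveform; `Inf` disables noise.
#' @param clock_offset constant delay of this channel, ms (rounded to the
#'   nearest sample when applied).
#' @param artifact_rate expected number of artifact bursts per minute.
#' @return A list of class `device_config`.
#' @export
device_config <- function(name, hp_cutoff = 0.5, lp_cutoff = 40,
                          sampling_rate = 1000, noise_snr = Inf,
                          clock_offset = 0, artifact_rate = 0) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (hp_cutoff < 0 || hp_cutoff >= lp_cutoff || lp_cutoff > sampling_rate / 2)
    stop("need 0 <= hp_cutoff < lp_cutoff <= sampling_rate/2")
  structure(list(name = as.character(name), hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff, sampling_rate = sampling_rate,
                 noise_snr = noise_snr, clock_offset = clock_offset,
                 artifact_rate = artifact_rate),
            class = "device_config")
}

#' Reference-amplifier preset (wide analog band)
#'
#' High-pass 0.016 Hz (a 10 s time constant), low-pass 250 Hz, 1000 Hz
#' sampling.
#' @param ... overrides passed to [device_config()].
#' @export
device_brainamp <- function(...) {
  args <- utils::modifyList(
    list(name = "BrainAmp", hp_cutoff = 0.016, lp_cutoff = 250,
         sampling_rate = 1000),
    list(...))
  do.call(device_config, args)
}

#' Low-cost-toolkit preset (narrow fixed analog band)
#'
#' High-pass 0.5 Hz, low-pass 40 Hz, 1000 Hz sampling.
#' @param ... overrides passed to [device_config()].
#' @export
device_bitalino <- function(...) {
  args <- utils::modifyList(
    list(name = "BITalino", hp_cutoff = 0.5, lp_cutoff = 40,
         sampling_rate = 1000),
    list(...))
  do.call(device_config, args)
}

#' Default blocked session schedule
#'
#' Seven consecutive blocks: three fixation baselines interleaved with four
#' picture blocks (pleasant/unpleasant), 300 s each. A picture block is
#' 60 presentations of 4 s plus a 1 s fixation cross.
#'
#' @param block_s block duration in seconds.
#' @return A data.frame with columns `label`, `condition`, `start_s`,
#'   `duration_s`.
#' @export
study_schedule <- function(block_s = 300) {
  cond <- c("fixation", "pleasant", "unpleasant", "fixation",
            "pleasant", "unpleasant", "fixation")
  data.frame(label = paste0("B", 1:7), condition = cond,
              start_s = (0:6) * block_s, duration_s = block_s,
              stringsAsFactors = FALSE)
}

#' Condition-dependent heart-rate shifts
#'
#' Additive HR shifts (beats/min) relative to the fixation baseline used by
#' the simulator: pleasant pictures slightly lower, unpleasant pictures
#' lowest, mirroring typical picture-viewing deceleration.
#' @return Named numeric vector over `fixation`, `pleasant`, `unpleasant`.
#' @export
condition_hr_shifts <- function() {
  c(fixation = 0, pleasant = 72.624 - 73.065, unpleasant = 71.515 - 73.065)
}

# internal: closed-form feature ground truth of the RR model.
# For a sinusoid of amplitude a (ms) and frequency f sampled every T seconds
# E[(dRR)^2] = 2 a^2 sin^2(pi f T); white jitter adds 2*jitter_sd^2.
# Spectral truth: each tone contributes a^2/2 ms^2; jitter is white on the
# beat grid with one-sided PSD 2*T*jitter_sd^2 ms^2/Hz, integrated over the
# standard band widths (0.11 Hz LF, 0.25 Hz HF).
rr_truth <- function(hr, lf_amp, hf_amp, jitter_sd) {
  mean_rr <- 60000 / hr
  T_s <- mean_rr / 1000
  rmssd <- sqrt(2 * lf_amp^2 * sin(pi * 0.1 * T_s)^2 +
                  2 * hf_amp^2 * sin(pi * 0.25 * T_s)^2 +
                  2 * jitter_sd^2)
  jit_psd <- 2 * T_s * jitter_sd^2
  list(true_mean_rr = mean_rr, true_hr = hr, true_rmssd = rmssd,
       true_lf = lf_amp^2 / 2 + jit_psd * 0.11,
       true_hf = hf_amp^2 / 2 + jit_psd * 0.25)
}

# internal: realize beats of the RR process on [t_start, t_end) ms with a
# fixed mean HR; modulation phase is tied to absolute time so consecutive
# blocks form one continuous process.
#
# Beats sample the modulation preferentially where intervals are short, so
# the beat-averaged interval of a naive realization falls below the nominal
# mean by ~var(mod)/mean_rr. The base interval carries that second-order
# compensation so that the beat-averaged RR (hence the measured HR) matches
# the configured rate.
rr_realize <- function(hr, lf_amp, hf_amp, jitter_sd, t_start_ms, t_end_ms) {
  mean_rr <- 60000 / hr
  # perturbation model: modulation must stay well inside the mean interval
  if (lf_amp + hf_amp + 4 * jitter_sd >= 0.9 * mean_rr)
    stop("modulation amplitude too large for the mean RR interval")
  var_mod <- (lf_amp^2 + hf_amp^2) / 2 + jitter_sd^2
  base_rr <- mean_rr + var_mod / mean_rr
  n_max <- ceiling((t_end_ms - t_start_ms) / mean_rr * 1.5) + 10
  times <- numeric(n_max)
  t <- t_start_ms
  k <- 0L
  while (t < t_end_ms) {
    k <- k + 1L
    times[k] <- t
    ts <- t / 1000
    rr <- base_rr + lf_amp * sin(2 * pi * 0.1 * ts) +
      hf_amp * sin(2 * pi * 0.25 * ts) +
      if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
    if (rr <= 0) stop("modulation amplitude too large: non-positive RR realized")
    t <- t + rr
  }
  onsets <- times[seq_len(k)]
  list(onsets = onsets, next_onset = t)
}

#' Generate a synthetic RR-interval series with known ground truth
#'
#' Realizes the sinusoidally modulated RR process beat by beat and returns
#' both the series and the analytically derived true feature values of the
#' generating model (mean RR, HR, RMSSD, LF, HF).
#'
#' @param params an [rr_process_params()]; `lf_amp`/`hf_amp`/`jitter_sd` are
#'   used as given (no between-subject scaling at this level).
#' @param duration duration in seconds (>= 60).
#' @param condition_shift additive HR shift in beats/min (see
#'   [condition_hr_shifts()]).
#' @param seed optional integer seed (defaults to `params$seed`).
#' @return A list with elements `rr` (an [rr_series()]) and `truth` (named
#'   list of true feature values).
#' @export
generate_rr_process <- function(params, duration, condition_shift = 0,
                                seed = params$seed) {
  stopifnot(inherits(params, "rr_process_params"))
  if (duration < 60) stop("duration must be at least 60 s")
  hr <- params$hr_mean + condition_shift
  if (hr <= 40 || hr >= 125) stop("shifted heart rate outside (40, 125) bpm")
  real <- with_seed(seed, rr_realize(hr, params$lf_amp, params$hf_amp,
                                     params$jitter_sd, 0, duration * 1000))
  on <- real$onsets
  iv <- diff(c(on, real$next_onset))
  list(rr = rr_series(on, iv, "detected", device = "truth"),
       truth = rr_truth(hr, params$lf_amp, params$hf_amp, params$jitter_sd))
}

# P-QRS-T template: per-component (offset ms from R, gaussian sigma ms,
# amplitude). R amplitude 1 is the strict per-beat maximum.
ecg_template <- function() {
  data.frame(comp = c("P", "Q", "R", "S", "T"),
             offset = c(-220, -28, 0, 28, 230),
             sigma = c(30, 9, 11, 9, 55),
             amp = c(0.10, -0.10, 1.00, -0.22, 0.30))
}

#' Render an ECG waveform from an RR-interval series
#'
#' The waveform is a sum of fixed Gaussian P-QRS-T bumps centred on the
#' cumulative beat times; the R bump (amplitude 1) is the strict per-beat
#' maximum.
#'
#' @param rr an [rr_series()] of positive intervals.
#' @param sampling_rate sampling rate in Hz (>= 250).
#' @param device,participant labels attached to the output signal.
#' @return An [ecg_signal()] with `round(duration * sampling_rate)` samples,
#'   where duration spans from time 0 to the end of the last interval.
#' @export
render_ecg <- function(rr, sampling_rate = 1000, device = "truth",
                       participant = "P01") {
  stopifnot(inherits(rr, "rr_series"))
  if (sampling_rate < 250) stop("sampling_rate must be at least 250 Hz")
  beats <- c(rr$onsets, rr$onsets[length(rr$onsets)] +
               rr$intervals[length(rr$intervals)])
  dur_ms <- beats[length(beats)]
  n <- round(dur_ms / 1000 * sampling_rate)
  x <- numeric(n)
  dt <- 1000 / sampling_rate
  tmpl <- ecg_template()
  for (ci in seq_len(nrow(tmpl))) {
    off <- tmpl$offset[ci]; sg <- tmpl$sigma[ci]; am <- tmpl$amp[ci]
    half <- 4 * sg
    for (b in beats) {
      c_ms <- b + off
      i0 <- max(1L, floor((c_ms - half) / dt) + 1L)
      i1 <- min(n, ceiling((c_ms + half) / dt) + 1L)
      if (i0 > i1) next
      tt <- (i0:i1 - 1) * dt
      x[i0:i1] <- x[i0:i1] + am * exp(-((tt - c_ms)^2) / (2 * sg^2))
    }
  }
  ecg_signal(x, sampling_rate, t0 = 0, device = device,
             participant = participant)
}

#' Pass an ECG waveform through a device acquisition model
#'
#' Applies the device's analog band as a zero-phase Butterworth band-pass
#' (3rd order per edge, forward-backward), delays the signal by the device
#' clock offset rounded to the nearest sample, then adds white measurement
#' noise at the configured SNR and, optionally, high-amplitude artifact
#' bursts (0.5-2 s transients emulating motion artifacts).
#'
#' @param ecg an [ecg_signal()].
#' @param device a [device_config()].
#' @param seed optional integer seed for noise and artifacts.
#' @return An [ecg_signal()] carrying attributes `applied_offset_ms` (the
#'   clock offset actually applied, after rounding to a sample) and
#'   `artifact_windows` (data.frame of injected burst spans in ms).
#' @export
apply_device_model <- function(ecg, device, seed = NULL) {
  stopifnot(inherits(ecg, "ecg_signal"), inherits(device, "device_config"))
  fs <- ecg$sampling_rate
  x <- ecg$samples
  if (device$hp_cutoff > 0) {
    bf <- signal::butter(3, device$hp_cutoff / (fs / 2), type = "high")
    x <- signal::filtfilt(bf, x)
  }
  if (device$lp_cutoff < fs / 2) {
    bf <- signal::butter(3, device$lp_cutoff / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  off_samp <- round(device$clock_offset * fs / 1000)
  if (off_samp > 0) {
    x <- c(rep(x[1], off_samp), x[seq_len(length(x) - off_samp)])
  } else if (off_samp < 0) {
    x <- c(x[(-off_samp + 1):length(x)], rep(x[length(x)], -off_samp))
  }
  art <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  x <- with_seed(seed, {
    if (is.finite(device$noise_snr)) {
      sigma <- sqrt(mean(x^2)) / 10^(device$noise_snr / 20)
      x <- x + stats::rnorm(length(x), 0, sigma)
    }
    if (device$artifact_rate > 0) {
      dur_min <- length(x) / fs / 60
      n_ev <- stats::rpois(1, device$artifact_rate * dur_min)
      if (n_ev > 0) {
        starts <- sort(stats::runif(n_ev, 0, length(x) / fs - 2))
        for (s in starts) {
          d <- stats::runif(1, 0.5, 2)
          i0 <- floor(s * fs) + 1L
          i1 <- min(length(x), i0 + round(d * fs) - 1L)
          k <- seq_len(i1 - i0 + 1L)
          # 4 Hz oscillation under a half-sine envelope: inside the analysis
          # band, so it survives processing filters and must be caught by
          # artifact flagging
          burst <- 8 * sin(pi * k / length(k)) * sin(2 * pi * 4 * k / fs)
          x[i0:i1] <- x[i0:i1] + burst
          art <- rbind(art, data.frame(start_ms = (i0 - 1) / fs * 1000,
                                       end_ms = (i1 - 1) / fs * 1000))
        }
      }
    }
    x
  })
  out <- ecg_signal(x, fs, t0 = ecg$t0, device = device$name,
                    participant = ecg$participant)
  attr(out, "applied_offset_ms") <- off_samp * 1000 / fs
  attr(out, "artifact_windows") <- art
  out
}

#' Simulate one participant's paired-device session
#'
#' Draws the participant's mean HR (truncated normal), per-participant
#' log-normal scalings of the LF/HF modulation amplitudes, and the device-B
#' clock offset, realizes one continuous beat sequence across the schedule
#' with condition-dependent HR shifts, renders the shared ECG waveform, and
#' passes it through both device models. [run_study()] iterates this
#' function so only one participant's recordings are in memory at a time.
#'
#' @param id participant label.
#' @param schedule block schedule data.frame.
#' @param params an [rr_process_params()].
#' @param device_a,device_b [device_config()]s.
#' @param offset_range_ms range of the device-B clock offset, ms.
#' @param seed integer seed.
#' @return List: `id`, `ecg_a`, `ecg_b`, `beats` (true [rr_series()]),
#'   `truth` (per-block ground-truth data.frame).
#' @export
simulate_participant <- function(id, schedule, params, device_a, device_b,
                                 offset_range_ms, seed) {
  shifts <- condition_hr_shifts()
  with_seed(seed, {
    # truncated normal draw keeps the detector's 40-125 bpm band reachable
    repeat {
      hr_i <- stats::rnorm(1, params$hr_mean, params$hr_between_subject_sd)
      if (hr_i > 45 && hr_i < 120) break
    }
    sdl <- params$amp_sdlog
    lf_amp_i <- params$lf_amp *
      if (sdl > 0) stats::rlnorm(1, -sdl^2 / 2, sdl) else 1
    hf_amp_i <- params$hf_amp *
      if (sdl > 0) stats::rlnorm(1, -sdl^2 / 2, sdl) else 1
    offset_b <- stats::runif(1, offset_range_ms[1], offset_range_ms[2])

    onsets <- numeric(0)
    truth <- NULL
    t_cur <- 0
    for (bi in seq_len(nrow(schedule))) {
      cond <- schedule$condition[bi]
      hr_b <- hr_i + shifts[[cond]] +
        if (params$block_hr_sd > 0) stats::rnorm(1, 0, params$block_hr_sd) else 0
      hr_b <- min(max(hr_b, 42), 123)
      t_end <- (schedule$start_s[bi] + schedule$duration_s[bi]) * 1000
      real <- rr_realize(hr_b, lf_amp_i, hf_amp_i, params$jitter_sd,
                         t_cur, t_end)
      onsets <- c(onsets, real$onsets)
      t_cur <- real$next_onset
      tr <- rr_truth(hr_b, lf_amp_i, hf_amp_i, params$jitter_sd)
      truth <- rbind(truth, data.frame(
        participant = id, block = schedule$label[bi], condition = cond,
        true_mean_rr = tr$true_mean_rr, true_hr = tr$true_hr,
        true_rmssd = tr$true_rmssd, true_lf = tr$true_lf,
        true_hf = tr$true_hf, true_lf_hf = tr$true_lf / tr$true_hf,
        clock_offset_ms = NA_real_, stringsAsFactors = FALSE))
    }
    iv <- diff(c(onsets, t_cur))
    beats <- rr_series(onsets, iv, "detected", device = "truth")
    raw <- render_ecg(beats, device_a$sampling_rate, device = "truth",
                      participant = id)
    dev_b <- device_b
    dev_b$clock_offset <- offset_b
    sa <- sample.int(2^31 - 2, 2)
    ecg_a <- apply_device_model(raw, device_a, seed = sa[1])
    ecg_b <- apply_device_model(raw, dev_b, seed = sa[2])
    truth$clock_offset_ms <- attr(ecg_b, "applied_offset_ms") -
      attr(ecg_a, "applied_offset_ms")
    list(id = id, ecg_a = ecg_a, ecg_b = ecg_b, beats = beats, truth = truth)
  })
}

#' Simulate a full paired-device study
#'
#' Generates `n_participants` sessions. Each participant has one continuous
#' ground-truth beat sequence with a condition-dependent HR shift; both
#' device recordings derive from the same beats and differ only by their
#' analog bands, measurement noise, a per-participant clock offset (drawn
#' uniformly from `offset_range_ms` and applied to device B), and artifact
#' bursts.
#'
#' For large sessions consider iterating [simulate_participant] via
#' [run_study()], which processes one participant at a time; this function
#' keeps all recordings in memory.
#'
#' @param n_participants number of participants (>= 2).
#' @param schedule block schedule data.frame (see [study_schedule()]).
#' @param params an [rr_process_params()].
#' @param device_a,device_b [device_config()]s for the two channels.
#' @param offset_range_ms range (ms) of the per-participant device-B clock
#'   offset.
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @return A list of class `study_recordings` with elements `participants`
#'   (list of per-participant recordings, beats and truth) and
#'   `ground_truth` (combined data.frame).
#' @export
simulate_study <- function(n_participants, schedule = study_schedule(),
                           params = rr_process_params(),
                           device_a = device_brainamp(),
                           device_b = device_bitalino(),
                           offset_range_ms = c(19, 28), seed = NULL) {
  if (n_participants < 2)
    stop("need at least 2 participants: agreement statistics undefined")
  seeds <- with_seed(seed, sample.int(2^31 - 2, n_participants))
  ids <- sprintf("P%02d", seq_len(n_participants))
  parts <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    parts[[i]] <- simulate_participant(ids[i], schedule, params, device_a,
                                       device_b, offset_range_ms, seeds[i])
  }
  gt <- do.call(rbind, lapply(parts, `[[`, "truth"))
  structure(list(participants = parts, ground_truth = gt,
                 schedule = schedule, seed = seed),
            class = "study_recordings")
}

#' @export
print.study_recordings <- function(x, ...) {
  cat(sprintf("<study_recordings> %d participants x %d blocks\n",
              length(x$participants), nrow(x$schedule)))
  invisible(x)
}
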