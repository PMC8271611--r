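# Per-block HRV dependent variables: HR, RMSSD, and spectral LF / HF / LF:HF
# from a cubic-spline resampled tachogram with a Welch periodogram.

#' Segment an RR-interval series into schedule blocks
#'
#' An interval belongs to a block iff its onset lies in
#' `[start, start + duration)` (half-open, so a boundary onset goes to the
#' later block).
#'
#' @param rr an [rr_series()].
#' @param blocks schedule data.frame with columns `label`, `condition`,
#'   `start_s`, `duration_s` (see [study_schedule()]).
#' @return Named list (by block label) of [rr_series()] objects; blocks with
#'   no intervals are present and empty.
#' @export
segment_blocks <- function(rr, blocks) {
  stopifnot(inherits(rr, "rr_series"))
  out <- vector("list", nrow(blocks))
  names(out) <- blocks$label
  for (i in seq_len(nrow(blocks))) {
    lo <- blocks$start_s[i] * 1000
    hi <- (blocks$start_s[i] + blocks$duration_s[i]) * 1000
    sel <- rr$onsets >= lo & rr$onsets < hi
    out[[i]] <- structure(list(onsets = rr$onsets[sel],
                               intervals = rr$intervals[sel],
                               flags = rr$flags[sel], device = rr$device),
                          class = "rr_series")
  }
  out
}

#' Mean heart rate of an RR series
#'
#' Defined through the mean interval, `HR = 60000 / mean(RR)` (robust to
#' partial intervals at block edges).
#'
#' @param rr an [rr_series()] with at least 2 intervals.
#' @return Heart rate in beats/min.
#' @export
compute_hr <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$intervals) < 2) stop("need at least 2 intervals")
  60000 / mean(rr$intervals)
}

#' Root mean square of successive RR differences
#'
#' `sqrt(mean((RR[i+1] - RR[i])^2))` over successive intervals of the block
#' only.
#'
#' @param rr an [rr_series()] with at least 3 intervals.
#' @return RMSSD in ms.
#' @export
compute_rmssd <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$intervals) < 3) stop("need at least 3 intervals")
  sqrt(mean(diff(rr$intervals)^2))
}

# internal: Welch PSD with Hann taper, one-sided density (units^2 per Hz).
# Per-segment mean removal; density normalised by fs * sum(w^2) so that
# summing psd * df over all frequencies recovers the signal variance.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  U <- sum(w^2)
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * fs * U)
  nf <- floor(seg_len / 2) + 1L
  one <- p[seq_len(nf)]
  # fold negative frequencies (all interior bins; Nyquist only when even)
  last <- if (seg_len %% 2 == 0) nf - 1L else nf
  if (last >= 2) one[2:last] <- 2 * one[2:last]
  list(freq = (seq_len(nf) - 1) * fs / seg_len, psd = one,
       df = fs / seg_len)
}

#' Spectral band powers of an RR series
#'
#' The RR series is resampled onto a uniform grid by cubic spline (the
#' tachogram), mean-removed, and a Welch periodogram (Hann taper, 120 s
#' segments, 50% overlap) is integrated over the LF and HF bands.
#'
#' @param rr an [rr_series()] spanning at least 120 s.
#' @param resample_rate tachogram sampling rate, Hz.
#' @param lf_band,hf_band band edges in Hz (half-open `[lo, hi)`).
#' @param seg_len_s Welch segment length, s.
#' @return List with `lf`, `hf` (ms^2) and `lf_hf` (`NA` when the HF power
#'   is zero).
#' @export
compute_band_powers <- function(rr, resample_rate = 4,
                                lf_band = c(0.04, 0.15),
                                hf_band = c(0.15, 0.40),
                                seg_len_s = 120) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$intervals)
  if (n < 4) stop("too few intervals for spectral analysis")
  span_s <- (rr$onsets[n] + rr$intervals[n] - rr$onsets[1]) / 1000
  if (span_s < 120) stop("block must span at least 120 s of intervals")
  grid <- seq(rr$onsets[1], rr$onsets[n], by = 1000 / resample_rate)
  tach <- stats::spline(rr$onsets, rr$intervals, xout = grid,
                        method = "fmm")$y
  tach <- tach - mean(tach)
  ps <- welch_psd(tach, resample_rate, seg_len = round(seg_len_s * resample_rate))
  in_band <- function(b) ps$freq >= b[1] & ps$freq < b[2]
  lf <- sum(ps$psd[in_band(lf_band)]) * ps$df
  hf <- sum(ps$psd[in_band(hf_band)]) * ps$df
  list(lf = lf, hf = hf, lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Per-block HRV feature row
#'
#' Computes all dependent variables of one block from a segmented RR series.
#' A block is usable when it holds at least 30 intervals and its HR lies in
#' the physiologic 40-125 beats/min band; spectral features additionally
#' require 120 s of intervals and are `NA` otherwise.
#'
#' @param rr_block an [rr_series()] restricted to one block.
#' @param min_intervals minimum interval count for a usable block.
#' @param ... passed to [compute_band_powers()].
#' @return One-row data.frame: `hr`, `rmssd`, `lf`, `hf`, `lf_hf`,
#'   `n_beats`, `fraction_interpolated`, `usable`.
#' @export
hrv_features <- function(rr_block, min_intervals = 30, ...) {
  n <- length(rr_block$intervals)
  row <- data.frame(hr = NA_real_, rmssd = NA_real_, lf = NA_real_,
                    hf = NA_real_, lf_hf = NA_real_, n_beats = n,
                    fraction_interpolated = NA_real_, usable = FALSE)
  if (n < min_intervals) return(row)
  row$hr <- compute_hr(rr_block)
  row$rmssd <- compute_rmssd(rr_block)
  row$fraction_interpolated <- mean(rr_block$flags == "interpolated")
  span_s <- (rr_block$onsets[n] + rr_block$intervals[n] - rr_block$onsets[1]) / 1000
  if (span_s >= 120) {
    bp <- compute_band_powers(rr_block, ...)
    row$lf <- bp$lf; row$hf <- bp$hf; row$lf_hf <- bp$lf_hf
  }
  row$usable <- row$hr > 40 & row$hr < 125
  row
}
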