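# Processing chain for paired ECG streams: zero-phase band-pass filtering,
# automated artifact flagging + interpolation, R-peak detection constrained
# to 40-125 bpm, beat correction (false-peak rejection, 5-period-mean
# missing-peak insertion), and cross-device alignment via matched R-peaks.

# physiologic rate band: 40-125 beats/min
RR_MAX_MS <- 60000 / 40   # 1500 ms
RR_MIN_MS <- 60000 / 125  # 480 ms

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a high-pass and a low-pass Butterworth filter of the stated order
#' forward-backward (zero phase), so filtering never displaces R-peaks. The
#' effective magnitude response is the squared one-pass response.
#'
#' @param ecg an [ecg_signal()].
#' @param hp high-pass cutoff, Hz.
#' @param lp low-pass cutoff, Hz.
#' @param order filter order per edge.
#' @return A filtered [ecg_signal()] of identical length.
#' @export
bandpass_filter <- function(ecg, hp = 1, lp = 40, order = 3) {
  stopifnot(inherits(ecg, "ecg_signal"))
  fs <- ecg$sampling_rate
  if (!(hp > 0 && hp < lp && lp < fs / 2))
    stop("need 0 < hp < lp < sampling_rate/2")
  # require a few settling lengths of the slowest edge
  if (length(ecg$samples) < 3 * fs / hp)
    stop("signal shorter than 3x the filter settling length")
  bf_hp <- signal::butter(order, hp / (fs / 2), type = "high")
  bf_lp <- signal::butter(order, lp / (fs / 2), type = "low")
  y <- signal::filtfilt(bf_hp, ecg$samples)
  y <- signal::filtfilt(bf_lp, y)
  out <- ecg
  out$samples <- as.numeric(y)
  out
}

#' Flag high-amplitude artifact windows
#'
#' Automated surrogate for manual artifact marking. The recording is tiled
#' into windows of `win` ms; each window is summarised by its peak absolute
#' deviation from the recording median. Windows whose summary exceeds
#' `z_thresh` robust SDs (MAD-based, floored at 5% of the median window
#' amplitude so the spiky-by-nature QRS complexes of a clean ECG are never
#' self-flagged) above the median window amplitude are flagged; adjacent
#' flagged windows are merged.
#'
#' @param ecg a filtered [ecg_signal()].
#' @param z_thresh robust z-score threshold.
#' @param win window length, ms.
#' @return Data.frame of class `artifact_mask` with columns `start_ms`,
#'   `end_ms` (non-overlapping, sorted). Constant signals yield an empty
#'   mask with a warning.
#' @export
flag_artifacts <- function(ecg, z_thresh = 6, win = 1000) {
  stopifnot(inherits(ecg, "ecg_signal"))
  x <- ecg$samples
  fs <- ecg$sampling_rate
  wlen <- max(1L, round(win * fs / 1000))
  nw <- ceiling(length(x) / wlen)
  idx <- rep(seq_len(nw), each = wlen, length.out = length(x))
  dev <- abs(x - stats::median(x))
  a_w <- as.numeric(tapply(dev, idx, max))
  med_a <- stats::median(a_w)
  scale <- max(stats::mad(a_w), 0.05 * med_a)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  class(empty) <- c("artifact_mask", "data.frame")
  if (scale == 0) {
    warning("constant signal: artifact scale undefined, empty mask")
    return(empty)
  }
  bad <- (a_w - med_a) / scale > z_thresh
  if (!any(bad)) return(empty)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  mask <- data.frame(
    start_ms = (starts[keep] - 1) * wlen / fs * 1000,
    end_ms = pmin(ends[keep] * wlen, length(x)) / fs * 1000)
  class(mask) <- c("artifact_mask", "data.frame")
  mask
}

#' Interpolate flagged artifact spans
#'
#' Replaces each flagged span by a natural cubic spline through the four
#' samples immediately adjacent on each side; unflagged samples are returned
#' bit-identical.
#'
#' @param ecg an [ecg_signal()].
#' @param mask an artifact mask from [flag_artifacts()].
#' @return An [ecg_signal()] with flagged spans replaced.
#' @export
interpolate_artifacts <- function(ecg, mask) {
  stopifnot(inherits(ecg, "ecg_signal"))
  if (is.null(mask) || nrow(mask) == 0) return(ecg)
  x <- ecg$samples
  fs <- ecg$sampling_rate
  total_ms <- sum(mask$end_ms - mask$start_ms)
  if (total_ms > 0.5 * length(x) / fs * 1000)
    stop("block unusable: artifact mask covers more than 50% of the signal")
  for (r in seq_len(nrow(mask))) {
    i0 <- max(1L, floor(mask$start_ms[r] * fs / 1000) + 1L)
    i1 <- min(length(x), ceiling(mask$end_ms[r] * fs / 1000))
    left <- seq(max(1L, i0 - 4L), i0 - 1L)
    right <- seq(i1 + 1L, min(length(x), i1 + 4L))
    left <- left[left >= 1 & left < i0]
    right <- right[right > i1 & right <= length(x)]
    anchors <- c(left, right)
    if (length(anchors) < 2) next  # span touches both edges; leave as is
    x[i0:i1] <- stats::spline(anchors, x[anchors], xout = i0:i1,
                              method = "natural")$y
  }
  out <- ecg
  out$samples <- x
  out
}

#' Detect R-peaks with a physiologic rate constraint
#'
#' Candidate peaks are local maxima of the positive-clipped squared signal
#' exceeding an adaptive threshold (0.4 times the local maximum of the
#' squared signal over a sliding ~2 s neighbourhood). A refractory spacing
#' of 480 ms (125 beats/min) is then enforced by keeping the larger peak of
#' any violating pair, implementing the allowed 40-125 bpm range.
#'
#' @param ecg a filtered [ecg_signal()] at least 10 s long.
#' @param thr_frac threshold as a fraction of the local squared-signal
#'   maximum.
#' @param chunk_s length of the local-maximum neighbourhood tile, s.
#' @return An [rpeak_series()], all flags `"detected"`, amplitudes taken
#'   from the filtered waveform.
#' @export
detect_r_peaks <- function(ecg, thr_frac = 0.4, chunk_s = 2) {
  stopifnot(inherits(ecg, "ecg_signal"))
  fs <- ecg$sampling_rate
  x <- ecg$samples
  if (length(x) < 10 * fs) stop("signal too short for peak detection (< 10 s)")
  x2 <- pmax(x, 0)^2
  clen <- max(1L, round(chunk_s * fs))
  nc <- ceiling(length(x2) / clen)
  cidx <- rep(seq_len(nc), each = clen, length.out = length(x2))
  cmax <- as.numeric(tapply(x2, cidx, max))
  # neighbourhood max over chunk and both neighbours avoids boundary misses
  nmax <- pmax(cmax, c(cmax[-1], 0), c(0, cmax[-nc]))
  thr <- thr_frac * nmax[cidx]
  n <- length(x2)
  is_max <- c(FALSE, x2[2:(n - 1)] >= x2[1:(n - 2)] &
                x2[2:(n - 1)] > x2[3:n], FALSE)
  cand <- which(is_max & x2 > thr)
  if (length(cand) < 5) stop("no usable rhythm: fewer than 5 peaks found")
  amp <- x[cand]
  # refractory: drop the smaller of any pair closer than RR_MIN_MS
  min_gap <- RR_MIN_MS * fs / 1000
  repeat {
    gaps <- diff(cand)
    v <- which(gaps < min_gap)
    if (!length(v)) break
    i <- v[1]
    drop <- if (amp[i + 1] < amp[i]) i + 1 else i
    cand <- cand[-drop]
    amp <- amp[-drop]
  }
  if (length(cand) < 5) stop("no usable rhythm: fewer than 5 peaks found")
  rpeak_series(ecg$t0 + (cand - 1) * 1000 / fs, "detected", amp,
               device = ecg$device)
}

#' Correct an R-peak series (false-peak rejection, missing-peak insertion)
#'
#' Two passes: (a) any inter-peak interval below 480 ms drops the peak with
#' the smaller amplitude support; (b) any interval above 1500 ms, or above
#' 1.5 times the mean of the five preceding corrected intervals, is treated
#' as containing missed beats and is filled with peaks stepped at that
#' five-interval mean (evenly distributed across the gap), flagged
#' `"interpolated"`. The output satisfies the 480-1500 ms interval
#' invariant and the operation is idempotent.
#'
#' @param peaks an [rpeak_series()] with at least 6 peaks.
#' @return A corrected [rpeak_series()].
#' @export
correct_beats <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$times) < 6) stop("need at least 6 detected peaks")
  t <- peaks$times; a <- peaks$amplitudes; f <- peaks$flags
  # (a) false-peak rejection
  i <- 2L
  while (i <= length(t)) {
    if (t[i] - t[i - 1] < RR_MIN_MS) {
      pair <- c(i - 1L, i)
      ap <- a[pair]
      # interpolated peaks (NA amplitude) yield first
      ap[is.na(ap)] <- -Inf
      drop <- pair[which.min(ap)]
      t <- t[-drop]; a <- a[-drop]; f <- f[-drop]
      i <- max(i - 1L, 2L)
    } else i <- i + 1L
  }
  if (length(t) < 2) stop("no usable rhythm after false-peak rejection")
  # (b) missing-peak insertion
  med_all <- stats::median(diff(t))
  out_t <- t[1]; out_a <- a[1]; out_f <- f[1]
  corr_iv <- numeric(0)
  warned <- FALSE
  for (i in 2:length(t)) {
    prev <- out_t[length(out_t)]
    gap <- t[i] - prev
    if (length(corr_iv) >= 1) {
      m5 <- mean(utils::tail(corr_iv, 5))
    } else {
      m5 <- med_all
      if (!warned && (gap > RR_MAX_MS || gap > 1.5 * m5)) {
        warning("no usable preceding intervals; falling back to the median interval")
        warned <- TRUE
      }
    }
    if (gap > RR_MAX_MS || gap > 1.5 * m5) {
      ns <- max(round(gap / m5), ceiling(gap / RR_MAX_MS))
      if (ns > 1) {
        step <- gap / ns
        ins <- prev + step * seq_len(ns - 1)
        out_t <- c(out_t, ins); out_a <- c(out_a, rep(NA_real_, ns - 1))
        out_f <- c(out_f, rep("interpolated", ns - 1))
        corr_iv <- c(corr_iv, rep(step, ns - 1))
        gap <- step
      }
    }
    out_t <- c(out_t, t[i]); out_a <- c(out_a, a[i]); out_f <- c(out_f, f[i])
    corr_iv <- c(corr_iv, gap)
  }
  rpeak_series(out_t, out_f, out_a, device = peaks$device)
}

#' Align two R-peak streams by their matched peak times
#'
#' For each peak of stream A the nearest unmatched peak of stream B within
#' `window` ms is its match (ties resolved to the earlier B peak; matching
#' is one-to-one, greedy in time order). The systematic inter-device offset
#' is the mean of the matched time differences `t_B - t_A`; stream B is
#' returned shifted by minus that offset.
#'
#' @param peaks_a,peaks_b [rpeak_series()] objects with at least 10 peaks
#'   each.
#' @param window half-width of the search window, ms (the full window spans
#'   2 * window + 1 ms around each A peak).
#' @return A list with `alignment` (class `alignment_result`: `n_matched`,
#'   `differences_ms`, `offset_ms`, `applied_shift_ms`) and `peaks_b`
#'   (the shifted series).
#' @export
align_streams <- function(peaks_a, peaks_b, window = 100) {
  stopifnot(inherits(peaks_a, "rpeak_series"), inherits(peaks_b, "rpeak_series"))
  ta <- peaks_a$times; tb <- peaks_b$times
  if (length(ta) < 10 || length(tb) < 10)
    stop("need at least 10 peaks in both streams")
  used_from <- 1L
  diffs <- numeric(0)
  for (i in seq_along(ta)) {
    lo <- ta[i] - window; hi <- ta[i] + window
    j <- used_from
    while (j <= length(tb) && tb[j] < lo) j <- j + 1L
    if (j > length(tb)) break
    best <- NA_integer_; bestd <- Inf
    k <- j
    while (k <= length(tb) && tb[k] <= hi) {
      d <- abs(tb[k] - ta[i])
      if (d < bestd) { bestd <- d; best <- k }  # strict: ties keep earlier
      k <- k + 1L
    }
    if (!is.na(best)) {
      diffs <- c(diffs, tb[best] - ta[i])
      used_from <- best + 1L
    }
  }
  if (length(diffs) < 0.5 * length(ta))
    stop("streams not concurrent: fewer than 50% of peaks matched")
  offset <- mean(diffs)
  res <- structure(list(n_matched = length(diffs), differences_ms = diffs,
                        offset_ms = offset, applied_shift_ms = -offset),
                   class = "alignment_result")
  shifted <- peaks_b
  shifted$times <- peaks_b$times - offset
  list(alignment = res, peaks_b = shifted)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d matched peaks, offset %.2f ms (B - A)\n",
              x$n_matched, x$offset_ms))
  invisible(x)
}

#' Shift an ECG signal by a whole number of samples
#'
#' Used to re-synchronise device B after alignment: a positive `shift_ms`
#' advances the signal (removes its delay). The offset is rounded to the
#' nearest sample; length is preserved with edge padding.
#'
#' @param ecg an [ecg_signal()].
#' @param shift_ms shift in ms (positive = advance).
#' @return The shifted [ecg_signal()].
#' @export
shift_signal <- function(ecg, shift_ms) {
  stopifnot(inherits(ecg, "ecg_signal"))
  fs <- ecg$sampling_rate
  s <- round(shift_ms * fs / 1000)
  x <- ecg$samples
  n <- length(x)
  if (s > 0) x <- c(x[(s + 1):n], rep(x[n], s))
  else if (s < 0) x <- c(rep(x[1], -s), x[seq_len(n + s)])
  out <- ecg
  out$samples <- x
  out
}
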