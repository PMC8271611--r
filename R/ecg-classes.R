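#' Uniformly sampled single-lead ECG signal
#'
#' Light-weight container for a single-channel ECG trace with device
#' provenance. Samples are amplitudes in arbitrary units (nominally mV) on a
#' uniform grid of `1000 / sampling_rate` milliseconds.
#'
#' @param samples numeric vector of amplitudes; must be finite.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in ms from recording start.
#' @param device device label (e.g. `"BrainAmp"`, `"BITalino"`).
#' @param participant participant label.
#' @return An object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, sampling_rate, t0 = 0, device = "device",
                       participant = "P01") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("ECG signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("ECG samples must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  structure(
    list(samples = samples, sampling_rate = sampling_rate, t0 = t0,
         device = as.character(device), participant = as.character(participant)),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %s / %s: %d samples @ %g Hz (%.1f s), t0 = %g ms\n",
              x$participant, x$device, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' Sample times of an ECG signal
#'
#' @param ecg an [ecg_signal()].
#' @return numeric vector of sample times in ms.
#' @export
sample_times <- function(ecg) {
  ecg$t0 + (seq_along(ecg$samples) - 1) * (1000 / ecg$sampling_rate)
}

#' R-peak event series
#'
#' Beat event times with per-beat quality flags. Peaks are either `"detected"`
#' (found in the waveform) or `"interpolated"` (inserted by beat correction).
#'
#' @param times strictly increasing peak times in ms.
#' @param flags character vector, one of `"detected"`, `"interpolated"`;
#'   recycled if length 1.
#' @param amplitudes waveform amplitude supporting each peak (`NA` for
#'   interpolated peaks); used to arbitrate false-peak rejection.
#' @param device source device label.
#' @return An object of class `rpeak_series`.
#' @export
rpeak_series <- function(times, flags = "detected", amplitudes = NA_real_,
                         device = "device") {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0))
    stop("peak times must be strictly increasing")
  flags <- rep_len(as.character(flags), length(times))
  if (!all(flags %in% c("detected", "interpolated")))
    stop("flags must be 'detected' or 'interpolated'")
  amplitudes <- rep_len(as.numeric(amplitudes), length(times))
  structure(list(times = times, flags = flags, amplitudes = amplitudes,
                 device = as.character(device)),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %s: %d peaks (%d interpolated), span %.1f s\n",
              x$device, length(x$times), sum(x$flags == "interpolated"),
              if (length(x$times) > 1) diff(range(x$times)) / 1000 else 0))
  invisible(x)
}

#' RR-interval series
#'
#' Inter-beat intervals with the onset time of each interval. An interval is
#' flagged `"interpolated"` when either bounding peak was inserted by beat
#' correction rather than detected.
#'
#' @param onsets interval onset times in ms (time of the opening peak).
#' @param intervals RR intervals in ms; `intervals[i]` spans `onsets[i]` to
#'   `onsets[i] + intervals[i]`.
#' @param flags per-interval flags (`"detected"` / `"interpolated"`).
#' @param device source device label.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(onsets, intervals, flags = "detected", device = "device") {
  onsets <- as.numeric(onsets); intervals <- as.numeric(intervals)
  if (length(onsets) != length(intervals))
    stop("onsets and intervals must have equal length")
  if (any(intervals <= 0)) stop("RR intervals must be positive")
  flags <- rep_len(as.character(flags), length(intervals))
  structure(list(onsets = onsets, intervals = intervals, flags = flags,
                 device = as.character(device)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s: %d intervals, mean RR %.1f ms\n",
              x$device, length(x$intervals),
              if (length(x$intervals)) mean(x$intervals) else NA_real_))
  invisible(x)
}

#' Convert an R-peak series to an RR-interval series
#'
#' @param peaks an [rpeak_series()] with at least two peaks.
#' @return An [rr_series()]; each interval inherits the `"interpolated"` flag
#'   when either bounding peak is interpolated.
#' @export
rr_from_peaks <- function(peaks) {
  n <- length(peaks$times)
  if (n < 2L) stop("need at least two peaks to form RR intervals")
  iv <- diff(peaks$times)
  fl <- ifelse(peaks$flags[-n] == "interpolated" |
                 peaks$flags[-1] == "interpolated",
               "interpolated", "detected")
  rr_series(peaks$times[-n], iv, fl, device = peaks$device)
}

# internal: restore RNG state on exit so seeded helpers do not perturb the
# caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
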