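# Orchestration: configuration, recording I/O, the per-participant
# processing chain, and the end-to-end study runner producing descriptive,
# ICC and Bland-Altman tables.

HRV_VARIABLES <- c("hr", "rmssd", "lf", "hf", "lf_hf")

#' Study configuration
#'
#' Collects every tunable of the simulation and analysis chain with its
#' default. The default devices carry 20 dB SNR measurement noise and 0.2
#' artifact bursts per minute; per-participant clock offsets are drawn from
#' 19-28 ms.
#'
#' @param n_participants number of simulated participants.
#' @param seed global integer seed.
#' @param schedule block schedule (see [study_schedule()]).
#' @param rr RR-process parameters (see [rr_process_params()]).
#' @param device_a,device_b device models (see [device_config()]).
#' @param offset_range_ms device-B clock offset range, ms.
#' @param filter processing band-pass: list `hp`, `lp` (Hz), `order`.
#' @param artifact artifact flagging: list `z_thresh`, `win_ms`.
#' @param align_window_ms half-width of the R-peak matching window, ms.
#' @param hrv feature settings: list `resample_rate`, `lf_band`, `hf_band`,
#'   `seg_len_s`, `min_intervals`.
#' @param agreement list `multiplier`, `log_transform`.
#' @param units `"ms"` (intervals ms, powers ms^2) or `"s"` for
#'   seconds-mode output tables.
#' @param out_dir optional output directory for result tables.
#' @param write_recordings also write the simulated raw recordings (CSV).
#' @param recordings optional data.frame `participant`, `path_a`, `path_b`
#'   to analyse recorded files instead of simulating.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 23, seed = 1,
                         schedule = study_schedule(),
                         rr = rr_process_params(),
                         device_a = device_brainamp(noise_snr = 20,
                                                    artifact_rate = 0.2),
                         device_b = device_bitalino(noise_snr = 20,
                                                    artifact_rate = 0.2),
                         offset_range_ms = c(19, 28),
                         filter = list(hp = 1, lp = 40, order = 3),
                         artifact = list(z_thresh = 6, win_ms = 1000),
                         align_window_ms = 100,
                         hrv = list(resample_rate = 4,
                                    lf_band = c(0.04, 0.15),
                                    hf_band = c(0.15, 0.40),
                                    seg_len_s = 120, min_intervals = 30),
                         agreement = list(multiplier = 1.96,
                                          log_transform = FALSE),
                         units = "ms", out_dir = NULL,
                         write_recordings = FALSE, recordings = NULL) {
  stopifnot(units %in% c("ms", "s"))
  structure(list(n_participants = n_participants, seed = seed,
                 schedule = schedule, rr = rr, device_a = device_a,
                 device_b = device_b, offset_range_ms = offset_range_ms,
                 filter = filter, artifact = artifact,
                 align_window_ms = align_window_ms, hrv = hrv,
                 agreement = agreement, units = units, out_dir = out_dir,
                 write_recordings = write_recordings,
                 recordings = recordings),
            class = "study_config")
}

# internal: strip classes so yaml round-trips plain structures
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.list(unclass(x)))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Write a study configuration to YAML
#' @param config a [study_config()].
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' Read a study configuration from YAML
#' @param path a YAML file written by [write_config()] (or hand-authored
#'   with the same fields; missing fields take their defaults).
#' @return A [study_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$schedule))
    args$schedule <- as.data.frame(raw$schedule, stringsAsFactors = FALSE)
  if (!is.null(raw$rr)) args$rr <- do.call(rr_process_params, raw$rr)
  if (!is.null(raw$device_a)) args$device_a <- do.call(device_config, raw$device_a)
  if (!is.null(raw$device_b)) args$device_b <- do.call(device_config, raw$device_b)
  if (!is.null(raw$recordings))
    args$recordings <- as.data.frame(raw$recordings, stringsAsFactors = FALSE)
  scalars <- setdiff(names(raw), c("schedule", "rr", "device_a", "device_b",
                                   "recordings"))
  for (nm in scalars) args[[nm]] <- simplify_field(raw[[nm]])
  do.call(study_config, args)
}

# yaml reads vectors as lists; flatten numeric leaves
simplify_field <- function(x) {
  if (is.list(x) && length(x) && all(vapply(x, is.atomic, TRUE)) &&
      is.null(names(x)))
    return(unlist(x))
  if (is.list(x)) return(lapply(x, simplify_field))
  x
}

#' Write an ECG recording to CSV
#'
#' The dialect carries device name, sampling rate and participant as `#`
#' comment lines, then `time_ms,amplitude` rows.
#'
#' @param ecg an [ecg_signal()].
#' @param path output path.
#' @export
write_recording <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# device: %s", ecg$device),
               sprintf("# sampling_rate: %.17g", ecg$sampling_rate),
               sprintf("# participant: %s", ecg$participant),
               "time_ms,amplitude"), con)
  tm <- sample_times(ecg)
  # %.17g guarantees doubles survive the text round trip bit-identically
  chunk <- 250000L
  for (i0 in seq(1L, length(tm), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(tm))
    writeLines(sprintf("%.17g,%.17g", tm[i0:i1], ecg$samples[i0:i1]), con)
  }
  invisible(path)
}

#' Read an ECG recording from CSV
#'
#' Reads the dialect of [write_recording()]. Timestamps must be present and
#' strictly increasing on a uniform grid; a gap exceeding two sample
#' periods is an error naming the offending time. Inputs not sampled at
#' `target_rate` are spline-resampled with a warning.
#'
#' @param path CSV file path.
#' @param format input format; only `"csv"` is supported in this build.
#' @param target_rate expected sampling rate, Hz.
#' @return An [ecg_signal()].
#' @export
read_recording <- function(path, format = c("csv", "xdf"), target_rate = 1000) {
  format <- match.arg(format)
  if (format == "xdf")
    stop("XDF containers are not supported in this build; export streams to CSV")
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- character(0)
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  meta <- function(key, default) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^# %s:", key), "", m[1])) else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_ms", "amplitude") %in% names(df)))
    stop("recording must have columns time_ms, amplitude")
  tm <- df$time_ms
  if (anyNA(tm) || anyNA(df$amplitude))
    stop("missing timestamps or amplitudes in ", path)
  dts <- diff(tm)
  if (any(dts <= 0))
    stop(sprintf("non-monotone timestamps in %s near t = %g ms", path,
                 tm[which(dts <= 0)[1]]))
  period <- stats::median(dts)
  gap <- which(dts > 2 * period)
  if (length(gap))
    stop(sprintf("timestamp gap of %g ms (> 2 sample periods) in %s at t = %g ms",
                 dts[gap[1]], path, tm[gap[1]]))
  fs <- 1000 / period
  x <- df$amplitude
  if (abs(fs - target_rate) > 1e-6) {
    warning(sprintf("resampling %s from %g Hz to %g Hz", path, fs, target_rate))
    grid <- seq(tm[1], tm[length(tm)], by = 1000 / target_rate)
    x <- stats::spline(tm, x, xout = grid, method = "fmm")$y
    fs <- target_rate
    tm <- grid
  }
  ecg_signal(x, fs, t0 = tm[1],
             device = meta("device", "device"),
             participant = meta("participant", "P01"))
}

#' Process one participant's paired recordings
#'
#' Stage order: provisional zero-phase band-pass on both raw streams,
#' R-peak detection for alignment, cross-device alignment (device B shifted
#' by the estimated offset), then the main chain per device - artifact
#' flagging and interpolation, peak detection, beat correction, block
#' segmentation and feature extraction. Because the band-pass is zero-phase
#' and the alignment shift is a whole number of samples, the provisional
#' filtered copies are reused as the main filtered signals.
#'
#' @param ecg_a,ecg_b raw [ecg_signal()]s of the two devices.
#' @param blocks schedule data.frame.
#' @param config a [study_config()] supplying the processing tunables.
#' @return List: `features` (long data.frame, one row per device x block),
#'   `alignment` (the [align_streams()] result), `artifact_masks` (per
#'   device), `log` (per-stage counts).
#' @export
process_participant <- function(ecg_a, ecg_b, blocks,
                                config = study_config()) {
  flt <- config$filter
  fa <- bandpass_filter(ecg_a, flt$hp, flt$lp, flt$order)
  fb <- bandpass_filter(ecg_b, flt$hp, flt$lp, flt$order)
  pk_a0 <- detect_r_peaks(fa)
  pk_b0 <- detect_r_peaks(fb)
  al <- align_streams(pk_a0, pk_b0, window = config$align_window_ms)
  fb <- shift_signal(fb, al$alignment$offset_ms)

  masks <- list()
  feats <- NULL
  logs <- list()
  for (side in c("a", "b")) {
    sig <- if (side == "a") fa else fb
    mask <- flag_artifacts(sig, z_thresh = config$artifact$z_thresh,
                           win = config$artifact$win_ms)
    masks[[sig$device]] <- mask
    sig <- interpolate_artifacts(sig, mask)
    pk <- correct_beats(detect_r_peaks(sig))
    rr <- rr_from_peaks(pk)
    segs <- segment_blocks(rr, blocks)
    for (bi in seq_len(nrow(blocks))) {
      row <- hrv_features(segs[[bi]],
                          min_intervals = config$hrv$min_intervals,
                          resample_rate = config$hrv$resample_rate,
                          lf_band = config$hrv$lf_band,
                          hf_band = config$hrv$hf_band,
                          seg_len_s = config$hrv$seg_len_s)
      feats <- rbind(feats, cbind(
        data.frame(participant = ecg_a$participant,
                   device = sig$device, block = blocks$label[bi],
                   condition = blocks$condition[bi],
                   stringsAsFactors = FALSE),
        row))
    }
    logs[[sig$device]] <- list(
      artifact_s = sum(mask$end_ms - mask$start_ms) / 1000,
      n_peaks = length(pk$times),
      n_interpolated = sum(pk$flags == "interpolated"))
  }
  list(features = feats, alignment = al$alignment,
       artifact_masks = masks, log = logs)
}

# internal: polynomial rolling hash of a serialized object (mod 2^31 - 1),
# for the run manifest
config_hash <- function(x) {
  bytes <- as.numeric(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full agreement study
#'
#' Simulates (or reads) all participants, processes each pair of
#' recordings, and computes the result tables: condition-level
#' descriptives (the acclimatization block B1 excluded from condition
#' means), ICC(2,1) with lower 95% CI overall and per block, repeated-
#' measures Bland-Altman with outside-LoA fractions, and the agreement
#' criteria verdicts. Fully reproducible from config + seed.
#'
#' @param config a [study_config()].
#' @return An object of class `study_results` with elements `features`,
#'   `descriptives`, `icc` (nested results), `icc_table`,
#'   `lower_ci_table`, `bland_altman` (per-variable results),
#'   `ba_table`, `criteria`, `alignments`, `exclusions`, `ground_truth`
#'   (simulation mode), `config`. Tables are also written as CSV when
#'   `config$out_dir` is set.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  sim <- is.null(config$recordings)
  if (sim) {
    if (config$n_participants < 2)
      stop("need at least 2 participants: agreement statistics undefined")
    n <- config$n_participants
    ids <- sprintf("P%02d", seq_len(n))
    seeds <- with_seed(config$seed, sample.int(2^31 - 2, n))
  } else {
    n <- nrow(config$recordings)
    if (n < 2)
      stop("need at least 2 participants: agreement statistics undefined")
    ids <- config$recordings$participant
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  features <- NULL
  alignments <- NULL
  exclusions <- data.frame(participant = character(0), reason = character(0))
  truth <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (sim) {
        p <- simulate_participant(ids[i], config$schedule, config$rr,
                                  config$device_a, config$device_b,
                                  config$offset_range_ms, seeds[i])
        if (isTRUE(config$write_recordings) && !is.null(out_dir)) {
          write_recording(p$ecg_a, file.path(out_dir,
            sprintf("%s_%s.csv", ids[i], p$ecg_a$device)))
          write_recording(p$ecg_b, file.path(out_dir,
            sprintf("%s_%s.csv", ids[i], p$ecg_b$device)))
        }
        truth <- rbind(truth, p$truth)
        process_participant(p$ecg_a, p$ecg_b, config$schedule, config)
      } else {
        ea <- read_recording(config$recordings$path_a[i])
        eb <- read_recording(config$recordings$path_b[i])
        ea$participant <- ids[i]; eb$participant <- ids[i]
        process_participant(ea, eb, config$schedule, config)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions <- rbind(exclusions, data.frame(
        participant = ids[i], reason = conditionMessage(res)))
      next
    }
    features <- rbind(features, res$features)
    alignments <- rbind(alignments, data.frame(
      participant = ids[i], offset_ms = res$alignment$offset_ms,
      n_matched = res$alignment$n_matched,
      artifact_s_a = res$log[[1]]$artifact_s,
      artifact_s_b = res$log[[2]]$artifact_s,
      interpolated_beats_a = res$log[[1]]$n_interpolated,
      interpolated_beats_b = res$log[[2]]$n_interpolated))
  }
  if (is.null(features)) stop("no participant could be processed")

  devices <- unique(features$device)
  descriptives <- study_descriptives(features)
  icc <- list(); ba <- list()
  blocks <- config$schedule$label
  for (v in HRV_VARIABLES) {
    tab <- paired_feature_table(features, v, devices)
    if (nrow(tab) < 5) next  # too few complete pairs for this variable
    per_scope <- list(overall = icc_2_1(tab))
    for (b in blocks) {
      tb <- paired_feature_table(features, v, devices, blocks = b)
      per_scope[[b]] <- if (nrow(tb) >= 5) icc_2_1(tb) else NULL
    }
    icc[[v]] <- per_scope[!vapply(per_scope, is.null, TRUE)]
    ba[[v]] <- bland_altman_repeated(
      tab, log_transform = isTRUE(config$agreement$log_transform),
      multiplier = config$agreement$multiplier)
  }
  if (!length(icc)) stop("no variable has enough complete pairs")
  icc_table <- icc_wide(icc, "estimate", c("overall", blocks))
  lower_table <- icc_wide(icc, "lower_ci_95", c("overall", blocks))
  ba_table <- do.call(rbind, lapply(names(ba), function(v) {
    r <- ba[[v]]
    data.frame(variable = v, bias = r$bias, loa_lower = r$loa_lower,
               loa_upper = r$loa_upper, sd_of_differences = r$sd_of_differences,
               outlier_pct = 100 * r$outlier_fraction,
               normality_p = r$normality_p, n = r$n,
               stringsAsFactors = FALSE)
  }))
  criteria <- evaluate_criteria(icc)

  results <- structure(list(
    features = features, descriptives = descriptives, icc = icc,
    icc_table = icc_table, lower_ci_table = lower_table,
    bland_altman = ba, ba_table = ba_table, criteria = criteria,
    alignments = alignments, exclusions = exclusions,
    ground_truth = truth, config = config), class = "study_results")
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

# internal: per-condition descriptive table; B1 (acclimatization) excluded
# from condition means, which average blocks within participant first
study_descriptives <- function(features) {
  f <- features[features$block != "B1" & features$usable, ]
  rows <- list()
  for (v in HRV_VARIABLES) {
    agg <- stats::aggregate(f[[v]],
      by = list(participant = f$participant, condition = f$condition,
                device = f$device),
      FUN = mean, na.rm = TRUE)
    res <- stats::aggregate(agg$x,
      by = list(condition = agg$condition, device = agg$device),
      FUN = function(z) c(mean = mean(z, na.rm = TRUE),
                          sd = stats::sd(z, na.rm = TRUE),
                          n = sum(is.finite(z))))
    rows[[v]] <- data.frame(variable = v, condition = res$condition,
                            device = res$device,
                            mean = res$x[, "mean"], sd = res$x[, "sd"],
                            n = res$x[, "n"], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: variable x scope wide table of an icc_result field, in percent
icc_wide <- function(icc, field, scopes) {
  out <- data.frame(variable = names(icc), stringsAsFactors = FALSE)
  for (s in scopes) {
    out[[s]] <- vapply(icc, function(per) {
      if (!is.null(per[[s]])) round(100 * per[[s]][[field]], 1) else NA_real_
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

# internal: seconds-mode conversion for output tables
convert_units <- function(features, units) {
  if (units != "s") return(features)
  features$rmssd <- features$rmssd / 1000
  features$lf <- features$lf / 1e6
  features$hf <- features$hf / 1e6
  features
}

#' Write study result tables to a directory
#'
#' @param results a `study_results` object from [run_study()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- results$config
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(convert_units(results$features, cfg$units), "features.csv")
  wr(results$descriptives, "descriptives.csv")
  wr(results$icc_table, "icc_table.csv")
  wr(results$lower_ci_table, "icc_lower_ci_table.csv")
  wr(results$ba_table, "bland_altman.csv")
  wr(results$criteria, "criteria.csv")
  wr(results$alignments, "alignments.csv")
  wr(results$exclusions, "exclusions.csv")
  wr(cfg$schedule, "blocks.csv")
  if (!is.null(results$ground_truth)) wr(results$ground_truth, "ground_truth.csv")
  devices <- unique(results$features$device)
  for (v in HRV_VARIABLES) {
    tab <- paired_feature_table(results$features, v, devices)
    if (nrow(tab) >= 3) {
      qq <- qq_data(tab$b - tab$a)
      wr(data.frame(theoretical = qq$theoretical, sample = qq$sample),
         sprintf("qq_%s.csv", v))
    }
  }
  manifest <- list(package = "hrvagree",
                   version = as.character(utils::packageVersion("hrvagree")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed,
                   # hash only the analysis-defining fields, not where the
                   # outputs happen to be written
                   config_hash = config_hash(unclass_deep(
                     cfg[setdiff(names(cfg), c("out_dir", "write_recordings"))])),
                   n_participants_in = if (!is.null(cfg$recordings))
                     nrow(cfg$recordings) else cfg$n_participants,
                   n_participants_used =
                     length(unique(results$features$participant)),
                   n_excluded = nrow(results$exclusions))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d participants (%d excluded), %d feature rows\n",
              length(unique(x$features$participant)), nrow(x$exclusions),
              nrow(x$features)))
  cat("\nICC(2,1) estimates (%):\n")
  print(x$icc_table, row.names = FALSE)
  cat("\nBland-Altman (repeated measures):\n")
  print(x$ba_table, row.names = FALSE, digits = 4)
  invisible(x)
}
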