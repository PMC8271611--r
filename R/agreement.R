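# Between-device agreement statistics: ICC(2,1) (two-way model, single
# measurement, absolute agreement) with its F-based lower 95% confidence
# bound, and Bland-Altman limits of agreement for repeated measurements of
# a quantity that varies between repeats.

#' Build a paired feature table for one variable
#'
#' Extracts device-A / device-B value pairs of one variable from a long
#' feature table (as produced by [process_participant()] /
#' [run_study()]). Rows with an unusable or missing side are dropped
#' pairwise and counted.
#'
#' @param features long data.frame with columns `participant`, `block`,
#'   `device`, the variable column, and `usable`.
#' @param variable variable column name (`"hr"`, `"rmssd"`, `"lf"`, `"hf"`,
#'   `"lf_hf"`).
#' @param devices character vector of the two device labels, in (A, B)
#'   order; defaults to the two labels present.
#' @param blocks optional block labels to restrict to.
#' @return Data.frame of class `paired_feature_table` with columns
#'   `participant`, `block`, `condition` (if present), `a`, `b`; attribute
#'   `n_dropped` counts excluded pairs.
#' @export
paired_feature_table <- function(features, variable, devices = NULL,
                                 blocks = NULL) {
  stopifnot(variable %in% names(features))
  if (is.null(devices)) devices <- unique(features$device)
  if (length(devices) != 2) stop("need exactly two devices")
  if (!is.null(blocks)) features <- features[features$block %in% blocks, ]
  fa <- features[features$device == devices[1], ]
  fb <- features[features$device == devices[2], ]
  key <- c("participant", "block")
  m <- merge(fa[, c(key, "condition", variable, "usable")],
             fb[, c(key, variable, "usable")],
             by = key, suffixes = c("_a", "_b"))
  va <- m[[paste0(variable, "_a")]]
  vb <- m[[paste0(variable, "_b")]]
  ok <- m$usable_a & m$usable_b & is.finite(va) & is.finite(vb)
  out <- data.frame(participant = m$participant[ok], block = m$block[ok],
                    condition = m$condition[ok], a = va[ok], b = vb[ok],
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant, out$block), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "variable") <- variable
  class(out) <- c("paired_feature_table", "data.frame")
  out
}

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random-effects model, single measurement, absolute agreement:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with `MSR`, `MSC`,
#' `MSE` the between-row, between-column and residual mean squares of the
#' two-way ANOVA decomposition of the n x k table. The lower 95% confidence
#' bound uses the F-based interval for the absolute-agreement single-rater
#' ICC with Satterthwaite degrees of freedom.
#'
#' Also evaluates the two conventional thresholds: estimate above 0.90
#' ("clinical" agreement) and lower bound above 0.75 (interchangeable use).
#'
#' @param table a [paired_feature_table()], or any data.frame/matrix whose
#'   columns `a` and `b` (or first two columns) hold the paired values.
#' @param alpha confidence level is `1 - alpha` (two-sided).
#' @return An object of class `icc_result`: `estimate`, `lower_ci_95`,
#'   `upper_ci_95`, `n_subjects`, `k`, `msr`, `msc`, `mse`, `degenerate`,
#'   `meets_clinical`, `meets_interchangeable`.
#' @export
icc_2_1 <- function(table, alpha = 0.05) {
  x <- icc_matrix(table)
  n <- nrow(x); k <- ncol(x)
  if (n < 5) stop("need at least 5 complete rows")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((x - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- (msr == 0 && msc == 0 && mse == 0)
  if (degenerate) {
    est <- 1; lower <- 1; upper <- 1
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse == 0 && msr > 0) {
      # error-free table: interval collapses to the estimate
      lower <- est; upper <- est
    } else {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- stats::qf(1 - alpha / 2, n - 1, v)
      lower <- n * (msr - f1 * mse) /
        (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
      f2 <- stats::qf(1 - alpha / 2, v, n - 1)
      upper <- n * (f2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    }
  }
  structure(list(estimate = est, lower_ci_95 = lower, upper_ci_95 = upper,
                 n_subjects = n, k = k, msr = msr, msc = msc, mse = mse,
                 degenerate = degenerate,
                 meets_clinical = est > 0.90,
                 meets_interchangeable = lower > 0.75),
            class = "icc_result")
}

# internal: coerce the various accepted table forms to an n x k matrix
icc_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  if (all(c("a", "b") %in% names(table)))
    return(cbind(a = table$a, b = table$b))
  as.matrix(table[, 1:2])
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.1f%% [lower 95%% CI %.1f%%], n = %d rows x %d raters\n",
              100 * x$estimate, 100 * x$lower_ci_95, x$n_subjects, x$k))
  cat(sprintf("  clinical (>90%%): %s; interchangeable (lower CI >75%%): %s\n",
              x$meets_clinical, x$meets_interchangeable))
  invisible(x)
}

#' Bland-Altman limits of agreement for repeated measurements
#'
#' Differences `d = B - A` are taken per (participant, block). The bias is
#' the grand mean of `d`. Because the measured quantity varies between
#' blocks, the SD of differences combines the within- and between-subject
#' components from a one-way ANOVA of `d` on participant:
#' `sd^2 = max(0, (MSB - MSW)/m0) + MSW` with `m0` the effective replicate
#' count for unbalanced data. LoA are `bias +/- multiplier * sd`; the
#' outside-LoA fraction is the share of differences strictly outside them.
#' With one block per participant (or when any participant has fewer than
#' two blocks) the estimator falls back to the classical pooled SD of `d`.
#'
#' @param table a [paired_feature_table()] or data.frame with columns
#'   `participant`, `a`, `b`.
#' @param log_transform log-transform the measurements before differencing
#'   (requires strictly positive values).
#' @param multiplier LoA multiplier (1.96 for 95% limits).
#' @return An object of class `ba_result`: `bias`, `loa_lower`,
#'   `loa_upper`, `sd_of_differences`, `outlier_fraction`, `n`,
#'   `normality_p`, `log_transformed`, `method` (`"repeated"` or
#'   `"classical"`).
#' @export
bland_altman_repeated <- function(table, log_transform = FALSE,
                                  multiplier = 1.96) {
  stopifnot(all(c("participant", "a", "b") %in% names(table)))
  a <- table$a; b <- table$b
  if (log_transform) {
    if (any(a <= 0 | b <= 0))
      stop("log transform requires strictly positive measurements")
    a <- log(a); b <- log(b)
  }
  d <- b - a
  n <- length(d)
  if (n < 2) stop("need at least 2 paired differences")
  g <- factor(table$participant)
  m_i <- tabulate(g)
  bias <- mean(d)
  if (any(m_i < 2)) {
    sdd <- stats::sd(d)
    method <- "classical"
  } else {
    gi <- tapply(d, g, mean)
    I <- nlevels(g)
    msb <- sum(m_i * (gi - bias)^2) / (I - 1)
    msw <- sum((d - gi[as.integer(g)])^2) / (n - I)
    m0 <- (n - sum(m_i^2) / n) / (I - 1)
    sdd <- sqrt(max(0, (msb - msw) / m0) + msw)
    method <- "repeated"
  }
  lo <- bias - multiplier * sdd
  hi <- bias + multiplier * sdd
  outfrac <- mean(d < lo | d > hi)
  norm_p <- if (stats::sd(d) == 0) NA_real_ else {
    dd <- if (n > 5000) d[round(seq(1, n, length.out = 5000))] else d
    tryCatch(stats::shapiro.test(dd)$p.value, error = function(e) NA_real_)
  }
  structure(list(bias = bias, loa_lower = lo, loa_upper = hi,
                 sd_of_differences = sdd, outlier_fraction = outfrac,
                 n = n, normality_p = norm_p,
                 log_transformed = log_transform, method = method),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %.5g, LoA [%.5g, %.5g], outside-LoA %.2f%% (n = %d)\n",
              x$method, x$bias, x$loa_lower, x$loa_upper,
              100 * x$outlier_fraction, x$n))
  invisible(x)
}

#' Shapiro-Wilk normality test of paired differences
#'
#' Thin, precondition-checked wrapper used by the agreement report. The
#' pipeline reports the p-value and proceeds with the untransformed
#' differences regardless of the outcome, recording the flag.
#'
#' @param differences numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
test_normality <- function(differences) {
  n <- length(differences)
  if (n < 3 || n > 5000) stop("need 3 <= n <= 5000 observations")
  if (stats::sd(differences) == 0) stop("degenerate sample: constant differences")
  st <- stats::shapiro.test(differences)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Normal quantile-quantile data for paired differences
#'
#' @param differences numeric vector, n >= 3.
#' @return List of plot-ready vectors: `theoretical` (standard-normal
#'   quantiles at `(i - 0.5)/n`) and `sample` (ordered differences).
#' @export
qq_data <- function(differences) {
  n <- length(differences)
  if (n < 3) stop("need at least 3 observations")
  list(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
       sample = sort(differences))
}

#' Evaluate the agreement criteria over ICC results
#'
#' Applies the two conventional thresholds (estimate > 90% for clinical
#' measurements; lower 95% CI > 75% for interchangeable use) to a set of
#' ICC results and summarises a verdict per variable/scope.
#'
#' @param icc_results named list of [icc_2_1()] results, or a nested list
#'   `variable -> scope -> icc_result`.
#' @return Data.frame with columns `variable`, `scope`, `icc_pct`,
#'   `lower_ci_pct`, `clinical_pass`, `interchangeable_pass`, `verdict`.
#' @export
evaluate_criteria <- function(icc_results) {
  rows <- list()
  add <- function(variable, scope, r) {
    verdict <- if (r$meets_clinical && r$meets_interchangeable)
      "good to excellent agreement"
    else if (r$meets_clinical) "clinical only"
    else if (r$meets_interchangeable) "interchangeable only"
    else "insufficient agreement"
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, scope = scope,
      icc_pct = round(100 * r$estimate, 1),
      lower_ci_pct = round(100 * r$lower_ci_95, 1),
      clinical_pass = r$meets_clinical,
      interchangeable_pass = r$meets_interchangeable,
      verdict = verdict, stringsAsFactors = FALSE)
  }
  for (v in names(icc_results)) {
    el <- icc_results[[v]]
    if (inherits(el, "icc_result")) add(v, "overall", el)
    else for (s in names(el)) add(v, s, el[[s]])
  }
  do.call(rbind, rows)
}
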