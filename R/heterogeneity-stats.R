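# Reference-anchored percentile-exceedance shift statistics. The same
# statistic serves flow cytometry (log10 fluorescence, thresholds at e.g.
# the 75th/99th percentiles of an early reference timepoint) and microscopy
# (relative intensity %, thresholds at e.g. the 95th/99th percentiles of the
# 0 h distribution): thresholds are frozen on the reference distribution,
# each timepoint's exceedance fraction is computed from ALL measured values,
# and the change is reported in percentage points.

#' Log10-transform fluorescence events
#'
#' Nonpositive values cannot be log-transformed; they are dropped and the
#' count of dropped events is reported, never silently.
#'
#' @param raw_values numeric vector of linear-scale fluorescence values.
#' @return list with `values` (log10 of the positive inputs) and `dropped`
#'   (number of nonpositive values removed).
#' @export
log10_events <- function(raw_values) {
  keep <- is.finite(raw_values) & raw_values > 0
  if (!any(keep)) {
    abort_comphet("log10_events: no positive values to transform")
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(sprintf("log10_events: dropped %d nonpositive value(s)", n_dropped))
  }
  list(values = log10(raw_values[keep]), dropped = n_dropped)
}

#' Percentile thresholds from a reference distribution
#'
#' Computes the threshold values at the requested percentile levels of the
#' reference-timepoint distribution, using the shared linear-interpolation
#' percentile convention. Thresholds must be computed from all measured
#' values of the reference sample, never from a display subsample.
#'
#' @param reference numeric vector, the reference-timepoint values.
#' @param levels strictly increasing percentile levels in (0, 100),
#'   e.g. `c(75, 99)` for cytometry or `c(95, 99)` for microscopy.
#' @return data.frame with columns `level` and `threshold` (nondecreasing).
#' @export
reference_thresholds <- function(reference, levels = c(75, 99)) {
  if (length(reference) == 0) {
    abort_comphet("reference_thresholds: empty reference sample")
  }
  stopifnot(all(levels > 0), all(levels < 100), !is.unsorted(levels, strictly = TRUE))
  if (length(reference) < 100) {
    warning(sprintf(
      "reference_thresholds: reference has only %d values; thresholds may be unstable",
      length(reference)))
  }
  data.frame(level = levels,
             threshold = percentile(reference, levels))
}

#' Fraction of values exceeding a threshold
#'
#' Strict exceedance: `100 * #{v > threshold} / n`. With continuous data the
#' strict/non-strict choice is immaterial; with ties it is fixed here as
#' strict.
#'
#' @param values numeric vector (nonempty).
#' @param threshold scalar threshold.
#' @return percent of values strictly above the threshold, in \[0, 100\].
#' @export
exceedance_fraction <- function(values, threshold) {
  if (length(values) == 0) abort_comphet("exceedance_fraction: empty sample")
  100 * sum(values > threshold) / length(values)
}

#' Distribution-shift report across timepoints
#'
#' For each strain: thresholds are set at the given percentile levels of the
#' reference-timepoint distribution, the exceedance fraction is computed for
#' every timepoint from the full sample, and the shift is summarized as
#' `delta_pp = fraction(late) - fraction(reference)` in percentage points.
#'
#' @param samples data.frame with columns `strain`, `timepoint_h`, `value`
#'   (one row per cell/event; values on a common scale within a strain,
#'   e.g. log10 fluorescence or relative intensity %).
#' @param reference_timepoint,late_timepoint timepoints (hours) anchoring
#'   the thresholds and the reported delta; both must be present for every
#'   strain.
#' @param levels percentile levels passed to [reference_thresholds()].
#' @return object of class `shift_report`: list with `thresholds` (strain,
#'   level, threshold), `fractions` (strain, timepoint_h, level, n,
#'   exceedance_pct) and `deltas` (strain, level, delta_pp).
#' @export
shift_report <- function(samples, reference_timepoint, late_timepoint,
                         levels = c(75, 99)) {
  stopifnot(is.data.frame(samples),
            all(c("strain", "timepoint_h", "value") %in% names(samples)))
  strains <- unique(samples$strain)
  thr_list <- list(); frac_list <- list(); delta_list <- list()
  for (s in strains) {
    sub <- samples[samples$strain == s, ]
    tps <- sort(unique(sub$timepoint_h))
    for (tp in c(reference_timepoint, late_timepoint)) {
      if (!tp %in% tps) {
        abort_comphet(sprintf(
          "shift_report: strain '%s' has no sample at timepoint %g h", s, tp))
      }
    }
    ref_values <- sub$value[sub$timepoint_h == reference_timepoint]
    thr <- reference_thresholds(ref_values, levels)
    thr_list[[s]] <- data.frame(strain = s, thr)
    fr <- do.call(rbind, lapply(tps, function(tp) {
      v <- sub$value[sub$timepoint_h == tp]
      data.frame(strain = s, timepoint_h = tp, level = thr$level,
                 n = length(v),
                 exceedance_pct = vapply(thr$threshold,
                                         function(th) exceedance_fraction(v, th),
                                         numeric(1)))
    }))
    frac_list[[s]] <- fr
    late <- fr[fr$timepoint_h == late_timepoint, ]
    ref <- fr[fr$timepoint_h == reference_timepoint, ]
    delta_list[[s]] <- data.frame(
      strain = s, level = thr$level,
      delta_pp = late$exceedance_pct[match(thr$level, late$level)] -
                 ref$exceedance_pct[match(thr$level, ref$level)])
  }
  structure(list(thresholds = do.call(rbind, c(thr_list, make.row.names = FALSE)),
                 fractions = do.call(rbind, c(frac_list, make.row.names = FALSE)),
                 deltas = do.call(rbind, c(delta_list, make.row.names = FALSE)),
                 reference_timepoint = reference_timepoint,
                 late_timepoint = late_timepoint, levels = levels),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("Distribution-shift report (reference %g h, late %g h)\n",
              x$reference_timepoint, x$late_timepoint))
  cat("Delta percentage points (late - reference):\n")
  print(x$deltas, row.names = FALSE)
  invisible(x)
}

#' Seeded subsample for display
#'
#' Draws `n` values uniformly without replacement for plotting (equal visual
#' density across panels). Display subsampling never feeds thresholds or
#' exceedance fractions, which always use the full sample. If `n` exceeds
#' the sample size the whole sample is returned with a warning.
#'
#' @param values numeric vector.
#' @param n subsample size (e.g. 250 cytometry events or 150 microscopy
#'   cells per strain and timepoint).
#' @param seed integer seed.
#' @return numeric vector of length `min(n, length(values))`.
#' @export
subsample_for_display <- function(values, n, seed = 1L) {
  if (n >= length(values)) {
    if (n > length(values)) {
      warning(sprintf(
        "subsample_for_display: requested %d of %d values; returning all",
        n, length(values)))
    }
    return(values)
  }
  withr::with_seed(seed, values[sample.int(length(values), n)])
}

#' Descriptive summary of a single-cell distribution
#'
#' Reports n, median, interquartile range and moment-based sample skewness
#' (`m3 / m2^(3/2)`). Skewness is a descriptive tail statistic here: a
#' right-skewed, unimodal profile whose skewness grows over time is the
#' expected signature of gradual heterogeneous induction.
#'
#' @param values numeric vector with at least 3 finite values.
#' @return data.frame with columns `n`, `median`, `iqr`, `skewness`.
#' @export
distribution_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    abort_comphet("distribution_summary: need at least 3 finite values")
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  data.frame(n = length(values), median = median(values),
             iqr = diff(percentile(values, c(25, 75))), skewness = skew)
}
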