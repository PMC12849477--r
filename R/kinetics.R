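# Population-level competence kinetics: transformation frequency with
# detection-limit censoring, maximum induction rate on the log10 scale,
# OD at peak transformability, and reporter-activity normalization/fitting.

#' Transformation frequency from plate counts
#'
#' Computes transformation frequency as transformant CFU per total viable
#' CFU, correcting for plating dilutions:
#' `tf = (selective_cfu * selective_dilution) / (total_cfu * total_dilution)`.
#' The no-DNA control plates define the spontaneous-reversion background;
#' the detection limit is the control-derived reversion frequency (or
#' `default_detection_limit` when the controls show zero revertants). An
#' entry whose selective count does not exceed the expected reversion
#' background is censored at the detection limit — censored entries carry
#' the limit value, never zero, so downstream log10 transforms are safe.
#'
#' @param pc data.frame of plate counts with columns `selective_cfu`,
#'   `total_cfu`, and optionally `selective_dilution`, `total_dilution`
#'   (default 1), `control_selective_cfu`, `control_total_cfu`, `time_h`,
#'   `condition`.
#' @param default_detection_limit detection limit used when controls give
#'   zero revertants; default `1e-9`, the spontaneous Trp+ reversion scale.
#' @return data.frame (`tf_series`): input identifier columns plus `tf`
#'   (frequency; the limit value where censored), `censored` (logical) and
#'   `detection_limit`.
#' @export
transformation_frequency <- function(pc, default_detection_limit = 1e-9) {
  stopifnot(is.data.frame(pc),
            all(c("selective_cfu", "total_cfu") %in% names(pc)))
  if (any(pc$total_cfu <= 0)) {
    abort_comphet("transformation_frequency: total_cfu must be positive")
  }
  sd_ <- if ("selective_dilution" %in% names(pc)) pc$selective_dilution else 1
  td_ <- if ("total_dilution" %in% names(pc)) pc$total_dilution else 1
  if (any(sd_ <= 0) || any(td_ <= 0)) {
    abort_comphet("transformation_frequency: dilution factors must be positive")
  }
  ctrl_sel <- if ("control_selective_cfu" %in% names(pc)) pc$control_selective_cfu else 0
  ctrl_tot <- if ("control_total_cfu" %in% names(pc)) pc$control_total_cfu else pc$total_cfu

  reversion <- ifelse(ctrl_tot > 0,
                      (ctrl_sel * sd_) / (ctrl_tot * td_), 0)
  limit <- pmax(reversion, default_detection_limit)
  tf_raw <- (pc$selective_cfu * sd_) / (pc$total_cfu * td_)
  # expected background revertant colonies on the selective plate
  expected_bg <- reversion * pc$total_cfu * td_ / sd_
  censored <- pc$selective_cfu <= expected_bg | pc$selective_cfu == 0
  out <- pc
  out$tf <- ifelse(censored, limit, pmin(tf_raw, 1))
  out$censored <- censored
  out$detection_limit <- limit
  out
}

#' Maximum competence induction rate
#'
#' Slope of log10-transformed transformation frequency per hour, estimated
#' as the maximum over sliding windows of `window_size` consecutive
#' non-censored points of the least-squares slope of `log10(tf)` vs time.
#' Censored entries never enter the fits.
#'
#' @param times numeric vector of times (hours).
#' @param tf numeric vector of transformation frequencies.
#' @param censored logical vector (default all `FALSE`); censored points are
#'   excluded.
#' @param window_size number of points per window (default 3).
#' @return list of class `induction_rate`: `max_log_slope` (log10 frequency
#'   per hour), `window` (`(t_start, t_end)` of the maximizing window), and
#'   `method`.
#' @export
max_induction_rate <- function(times, tf, censored = rep(FALSE, length(tf)),
                               window_size = 3) {
  stopifnot(length(times) == length(tf), length(censored) == length(tf),
            window_size >= 2)
  keep <- !censored & is.finite(tf) & tf > 0
  tt <- times[keep]; yy <- log10(tf[keep])
  ord <- order(tt); tt <- tt[ord]; yy <- yy[ord]
  n <- length(tt)
  if (n < window_size) {
    abort_comphet(sprintf(
      "max_induction_rate: need >= %d non-censored points, got %d",
      window_size, n))
  }
  best_slope <- -Inf; best_window <- c(NA_real_, NA_real_)
  for (i in seq_len(n - window_size + 1)) {
    j <- i:(i + window_size - 1)
    x <- tt[j]; y <- yy[j]
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    if (is.finite(sl) && sl > best_slope) {
      best_slope <- sl; best_window <- c(x[1], x[length(x)])
    }
  }
  structure(list(max_log_slope = best_slope, window = best_window,
                 method = sprintf("sliding %d-point least squares on log10(tf)",
                                  window_size)),
            class = "induction_rate")
}

#' @export
print.induction_rate <- function(x, ...) {
  cat(sprintf("Max induction rate: %.4g log10 units/h over window [%g, %g] h (%s)\n",
              x$max_log_slope, x$window[1], x$window[2], x$method))
  invisible(x)
}

#' Optical density at peak transformability
#'
#' Finds the earliest time of maximal (non-censored) transformation
#' frequency and reports the culture OD at that time. OD is linearly
#' interpolated when the OD series is not sampled at the TF times.
#'
#' @param od_times,od the OD600 time series.
#' @param tf_times,tf the transformation-frequency series.
#' @param censored logical vector; censored TF entries are ignored.
#' @return list with `od`, `peak_time`, `peak_tf`.
#' @export
od_at_peak_tf <- function(od_times, od, tf_times, tf,
                          censored = rep(FALSE, length(tf))) {
  stopifnot(length(od_times) == length(od), length(tf_times) == length(tf))
  keep <- !censored & is.finite(tf)
  if (!any(keep)) {
    abort_comphet("od_at_peak_tf: all transformation frequencies are censored")
  }
  tt <- tf_times[keep]; ff <- tf[keep]
  peak_idx <- which(ff == max(ff))
  peak_time <- min(tt[peak_idx])          # ties -> earliest time
  od_val <- approx(od_times, od, xout = peak_time, rule = 2)$y
  list(od = od_val, peak_time = peak_time, peak_tf = max(ff))
}

#' Normalize reporter fluorescence to the biomass channel
#'
#' Pointwise ratio of the fluorogenic reporter signal (MUG channel) to the
#' lipophilic biomass dye signal (Nile Red channel), correcting promoter
#' activity for culture growth. Biomass values at or below `floor` cannot
#' normalize and are masked to `NA` with a warning.
#'
#' @param mug numeric vector, reporter fluorescence.
#' @param nilered numeric vector, biomass fluorescence (same length).
#' @param floor biomass values `<= floor` are masked (default 0).
#' @return numeric vector `mug / nilered` with masked points as `NA`.
#' @export
normalize_reporter <- function(mug, nilered, floor = 0) {
  stopifnot(length(mug) == length(nilered))
  bad <- !is.finite(nilered) | nilered <= floor
  if (all(bad)) {
    abort_comphet("normalize_reporter: all biomass values at or below the floor")
  }
  if (any(bad)) {
    warning(sprintf("normalize_reporter: masked %d point(s) with biomass <= floor",
                    sum(bad)))
  }
  out <- mug / nilered
  out[bad] <- NA_real_
  out
}

#' Peak promoter-induction time versus inoculation density
#'
#' Tabulates the steepest-slope (peak) time of each condition's fitted
#' reporter curve against its initial inoculation density, sorted by
#' density, and reports the Spearman rank correlation descriptively (an
#' inverse relation means denser inocula reach peak induction earlier).
#'
#' @param fits list of [fit_four_pl()] results, one per condition.
#' @param initial_od numeric vector of initial OD600 values, same length.
#' @return list of class `peak_time_table`: `table` (data.frame `initial_od`,
#'   `peak_time_h`, sorted by density), `rank_correlation` (Spearman rho;
#'   `NA` with a `degenerate` flag when all densities tie).
#' @export
peak_time_vs_inoculum <- function(fits, initial_od) {
  if (length(fits) < 2) {
    abort_comphet("peak_time_vs_inoculum: need at least 2 conditions")
  }
  stopifnot(length(fits) == length(initial_od))
  peak <- vapply(fits, function(f) f$peak_time, numeric(1))
  ord <- order(initial_od)
  tab <- data.frame(initial_od = initial_od[ord], peak_time_h = peak[ord])
  degenerate <- length(unique(initial_od)) < 2 || length(unique(peak)) < 2
  rho <- if (degenerate) NA_real_ else {
    cor(initial_od, peak, method = "spearman")
  }
  if (degenerate) {
    warning("peak_time_vs_inoculum: degenerate input (tied densities or peak times); correlation undefined")
  }
  structure(list(table = tab, rank_correlation = rho, degenerate = degenerate),
            class = "peak_time_table")
}

#' @export
print.peak_time_table <- function(x, ...) {
  cat("Peak induction time vs inoculation density\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Spearman rank correlation: %s\n",
              ifelse(is.na(x$rank_correlation), "undefined",
                     sprintf("%.3f", x$rank_correlation))))
  invisible(x)
}
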