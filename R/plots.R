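#' Beeswarm-style shift figure
#'
#' One panel per strain: subsampled single-cell values (jittered points) per
#' timepoint, dashed horizontal lines at the reference-percentile thresholds,
#' and an annotation with the percentage-point change above each threshold
#' between the reference and late timepoints. Points come from the seeded
#' display subsample; thresholds and deltas always come from the full
#' samples.
#'
#' @param samples data.frame with columns `strain`, `timepoint_h`, `value`.
#' @param shift a [shift_report()] computed from the same samples.
#' @param subsample_n points drawn per strain and timepoint (e.g. 250
#'   cytometry events or 150 microscopy cells).
#' @param seed integer seed for the display subsample.
#' @param value_lab y-axis label.
#' @return a ggplot object.
#' @export
plot_shift_beeswarm <- function(samples, shift, subsample_n = 250, seed = 1L,
                                value_lab = "value") {
  stopifnot(inherits(shift, "shift_report"))
  pieces <- list()
  for (s in unique(samples$strain)) {
    for (tp in sort(unique(samples$timepoint_h[samples$strain == s]))) {
      v <- samples$value[samples$strain == s & samples$timepoint_h == tp]
      sub <- suppressWarnings(
        subsample_for_display(v, subsample_n,
                              seed = derive_seed(seed, paste(s, tp))))
      pieces[[paste(s, tp)]] <- data.frame(strain = s, timepoint_h = tp,
                                           value = sub)
    }
  }
  pts <- do.call(rbind, pieces)
  ann <- do.call(rbind, lapply(split(shift$deltas, shift$deltas$strain),
    function(d) data.frame(
      strain = d$strain[1],
      label = paste(sprintf("delta >%gth: %+.2f pp", d$level, d$delta_pp),
                    collapse = "\n"))))
  ggplot2::ggplot(pts, ggplot2::aes(x = factor(timepoint_h), y = value)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(data = shift$thresholds,
                        ggplot2::aes(yintercept = threshold, linetype = factor(level)),
                        colour = "blue") +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = label),
                       x = -Inf, y = Inf, hjust = -0.05, vjust = 1.2,
                       size = 2.8, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~strain) +
    ggplot2::labs(x = "time post-inoculation (h)", y = value_lab,
                  linetype = "reference\npercentile") +
    ggplot2::theme_bw()
}
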