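#' Plot a positional motif profile
#'
#' Line plot of per-bin motif frequency against position relative to the
#' anchor (TTS or TSS), the classic terminal-signal profile.
#'
#' @param object A `txa_profile` from [positional_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot txa_profile
#' @export
autoplot.txa_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_center,
                                  y = .data$frequency)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = sprintf("Position relative to %s (bp)",
                  toupper(attr(object, "anchor"))),
      y = sprintf("Frequency per %d bp bin", attr(object, "bin")),
      title = attr(object, "motif")) +
    ggplot2::theme_minimal()
}

#' Plot cumulative PAS curves around TSSs
#'
#' Upstream (dashed) versus downstream (solid) cumulative PAS frequency;
#' a faster-rising upstream curve indicates PAS depletion in the
#' direction of transcription.
#'
#' @param object A `txa_cumcurve` from [cumulative_pas()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot txa_cumcurve
#' @export
autoplot.txa_cumcurve <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("upstream", "downstream"),
                        names_to = "side", values_to = "cumulative")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$cumulative,
                                  linetype = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(upstream = "dashed",
                                              downstream = "solid")) +
    ggplot2::labs(x = "Distance from TSS (bp)",
                  y = "Cumulative PAS per TSS", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an alternative-splicing summary
#'
#' Bar chart of event counts per class, labelled with each class's share
#' of all events.
#'
#' @param object A `txa_as_summary` from [summarize_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot txa_as_summary
#' @export
autoplot.txa_as_summary <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(class = factor(.data$class, levels = AS_CLASSES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n_events)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$pct_events)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "AS events") +
    ggplot2::theme_minimal()
}

#' Plot a 3'-extension report
#'
#' Histogram of per-transcript extension lengths.
#'
#' @param object A `txa_extension` from [extend_three_prime()].
#' @param binwidth Histogram bin width in bp.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot txa_extension
#' @export
autoplot.txa_extension <- function(object, binwidth = 25, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#7570b3",
                            colour = "white") +
    ggplot2::labs(x = "3' extension (bp)", y = "Transcripts") +
    ggplot2::theme_minimal()
}

#' Plot intergenic-distance distribution
#'
#' Log-scale histogram of intergenic distances with the median marked,
#' the standard view of genome compactness.
#'
#' @param ann A `txa_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_intergenic <- function(ann, ...) {
  igd <- intergenic_distances(ann)
  d <- filter(igd$distances, .data$distance > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = igd$median, colour = "red") +
    ggplot2::labs(x = "Intergenic distance (bp, log scale)", y = "Gene pairs",
                  subtitle = sprintf("median = %.0f bp", igd$median)) +
    ggplot2::theme_minimal()
}
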