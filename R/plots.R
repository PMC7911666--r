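#' Plot replication-timing profiles along a chromosome
#'
#' Smoothed log2(early/late) values against genomic position, one line per
#' sample, faceted by chromosome. Bins above zero replicate early, below
#' zero late.
#'
#' @param profiles Long tibble from [bin_ratio_tracks()] (`chrom`, `start`,
#'   `sample`, `value`).
#' @param chroms Optional subset of chromosomes to show.
#' @return A ggplot object.
#' @export
plot_rt_profile <- function(profiles, chroms = NULL) {
  df <- if (is.null(chroms)) profiles else profiles[profiles$chrom %in% chroms, ]
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$start / 1e6, y = .data$value,
                               colour = .data$sample)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2(early/late)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Genome-wide switching plot
#'
#' Per-segment replication-timing delta against position, coloured by switch
#' class, faceted by chromosome.
#'
#' @param object An `rt_switch_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rt_switch_fit <- function(object, ...) {
  df <- object$calls[object$calls$class != "masked", ]
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$delta, colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_manual(values = c(EtoL = "#d73027", LtoE = "#4575b4",
                                            EtoE = "grey75", LtoL = "grey55")) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "RT delta (mut - ctrl)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Fiber analysis plots
#'
#' Histograms of per-track fork speeds and inter-origin distances.
#'
#' @param object A `fiber_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fiber_analysis <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(what = "fork speed (kb/min)",
                   value = object$speeds$speed_kb_per_min),
    tibble::tibble(what = "inter-origin distance (kb)",
                   value = object$distances$distance_kb)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~what, scales = "free") +
    ggplot2::labs(x = NULL, y = "tracks") +
    ggplot2::theme_minimal()
}
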