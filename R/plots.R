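# ggplot2 views of the main result types.

#' Plot a coverage track with called units
#'
#' @param track A [coverage_track()].
#' @param units Optional unit tibble overlaid as segments.
#' @param chrom,start,end Region to draw (defaults to the track's extent).
#' @return A ggplot.
#' @export
plot_coverage <- function(track, units = NULL, chrom = NULL, start = NULL,
                          end = NULL) {
  r <- track$runs
  chrom <- chrom %||% r$chrom[1]
  r <- r[r$chrom == chrom, , drop = FALSE]
  start <- start %||% min(r$start)
  end <- end %||% max(r$end)
  r <- r[r$end > start & r$start < end, , drop = FALSE]
  p <- ggplot2::ggplot(r) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = .data$value),
                       fill = "grey35") +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom), y = "coverage",
                  title = sprintf("%s (%s strand)", track$sample_id, track$strand)) +
    ggplot2::theme_minimal()
  if (!is.null(units) && nrow(units) > 0) {
    u <- units[units$chrom == chrom & units$end > start & units$start < end, ]
    p <- p + ggplot2::geom_segment(
      data = u,
      ggplot2::aes(x = .data$start, xend = .data$end, y = -0.05, yend = -0.05),
      linewidth = 2, colour = "firebrick"
    )
  }
  p
}

#' Abundance profiles behind dynamics calls
#'
#' @param object A `dynamics_calls` tibble.
#' @param abundances The unit-by-sample abundance tibble that produced it.
#' @param sample_order Optional ordered sample labels.
#' @param ... Unused.
#' @return A ggplot of abundance across the sample series, one line per
#'   unit, coloured by dynamics label.
#' @export
autoplot.dynamics_calls <- function(object, abundances, sample_order = NULL, ...) {
  d <- dplyr::left_join(abundances, object[, c("unit_id", "label")], by = "unit_id")
  if (!is.null(sample_order)) {
    d$sample_id <- factor(d$sample_id, levels = sample_order)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$abundance,
                                  group = .data$unit_id, colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = NULL, y = "normalized abundance", colour = "dynamics") +
    ggplot2::theme_minimal()
}

#' Ranked candidate-TF bar chart
#'
#' @param object A `candidate_tfs` tibble.
#' @param ... Unused.
#' @return A ggplot of signed log2 fold change by rank.
#' @export
autoplot.candidate_tfs <- function(object, ...) {
  d <- dplyr::mutate(object, tf = stats::reorder(.data$tf, -abs(.data$log2fc)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf, y = .data$log2fc,
                                  fill = .data$log2fc > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "log2 fold change (b / a)") +
    ggplot2::theme_minimal()
}

#' Dip profile around an anchor
#'
#' @param signal A [coverage_track()] of binned signal.
#' @param peak One-row interval tibble (region drawn).
#' @param dip Optional one-row dip tibble from [detect_dip()]; the center is
#'   marked.
#' @param anchor Optional anchor position (dashed line).
#' @return A ggplot.
#' @export
plot_dip <- function(signal, peak, dip = NULL, anchor = NULL) {
  bins <- signal$runs[signal$runs$chrom == peak$chrom &
                        signal$runs$end > peak$start &
                        signal$runs$start < peak$end, , drop = FALSE]
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                          y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s position (bp)", peak$chrom),
                  y = "binned signal") +
    ggplot2::theme_minimal()
  if (!is.null(anchor)) {
    p <- p + ggplot2::geom_vline(xintercept = anchor, linetype = "dashed")
  }
  if (!is.null(dip) && nrow(dip) == 1) {
    p <- p + ggplot2::geom_vline(xintercept = dip$center, colour = "firebrick")
  }
  p
}
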