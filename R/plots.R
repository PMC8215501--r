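#' Plot stratified precision/recall/F1
#'
#' Bar panels of precision, recall and F1 per SV type, faceted by TRR
#' status, from a [stratified_metrics()] table (the `size_bin = "all"`
#' slice by default).
#'
#' @param metrics Output of [stratified_metrics()] (possibly several
#'   callsets row-bound, distinguished by `source`).
#' @param bin Which size bin slice to show (default `"all"`).
#' @return A ggplot object.
#' @export
plot_stratified_metrics <- function(metrics, bin = "all") {
  x <- metrics |>
    dplyr::filter(.data$size_bin == bin) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$svtype, y = .data$value,
                                  fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(metric ~ trr_status) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "SV detection performance in/outside TRRs") +
    ggplot2::theme_minimal()
}

#' Plot F1 by SV size bin
#'
#' @param metrics Output of [stratified_metrics()].
#' @return A ggplot object with one panel per type and TRR status.
#' @export
plot_size_f1 <- function(metrics) {
  x <- dplyr::filter(metrics, .data$size_bin != "all")
  x$size_bin <- factor(x$size_bin, levels = unique(metrics$size_bin))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$size_bin, y = .data$f1,
                                  fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(svtype ~ trr_status) +
    ggplot2::labs(x = "SV size (bp)", y = "F1",
                  title = "F1 by SV size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a concurrent-detection histogram
#'
#' @param concurrent Output of [concurrent_detection()] (optionally
#'   row-bound over strata with an extra grouping column).
#' @param fill Optional name of a grouping column.
#' @return A ggplot object.
#' @export
plot_concurrent_detection <- function(concurrent, fill = NULL) {
  aes <- if (is.null(fill)) {
    ggplot2::aes(x = factor(.data$n_pipelines), y = .data$proportion)
  } else {
    ggplot2::aes(x = factor(.data$n_pipelines), y = .data$proportion,
                 fill = .data[[fill]])
  }
  ggplot2::ggplot(concurrent, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "number of pipelines detecting the benchmark SV",
                  y = "proportion of benchmark SVs",
                  title = "Concurrent detection") +
    ggplot2::theme_minimal()
}

#' @rdname plot_overlap
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_summary <- function(object, ...) plot_overlap(object)

#' Plot a callset overlap summary
#'
#' Stacked per-set bars of the overlap decomposition: for each callset, how
#' many of its records were also found in each combination of the other
#' callsets.
#'
#' @param object An `"overlap_summary"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_overlap <- function(object, ...) {
  x <- tidy.overlap_summary(object)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$set, y = .data$count,
                                  fill = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "records",
                  title = "Callset overlap decomposition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
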