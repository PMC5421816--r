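#' Plot merge heights of a clustering run
#'
#' Histogram of the tetrad-table merge distances; on well-separated data the
#' within-OTU merges pile up near zero, well below the stop distance.
#'
#' @param fit A `pbp_hc` object (or tetrad tibble).
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_merge_heights <- function(fit, bins = 40) {
  events <- if (inherits(fit, "pbp_hc")) fit$events else fit
  ggplot2::ggplot(events, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::labs(x = "merge distance", y = "merge steps",
                  title = "Hierarchical merge heights")
}

#' Number of clusters as a function of the distance threshold
#'
#' @param object A `pbp_hc` object.
#' @param ... Unused.
#' @return A ggplot (step curve of cluster counts against threshold).
#' @export
autoplot.pbp_hc <- function(object, ...) {
  d <- sort(object$events$distance)
  curve <- tibble(threshold = c(0, d, object$d_up),
                  clusters = c(object$n, object$n - seq_along(d),
                               object$n - length(d)))
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$threshold, y = .data$clusters)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance threshold", y = "clusters",
                  title = "Cluster count across thresholds")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rarefaction curve
#'
#' Expected OTU richness in random subsamples of increasing depth, per
#' partition threshold.
#'
#' @param x A `pbp_otu` pipeline result.
#' @param depths Subsample depths (defaults to 20 points up to the read
#'   count).
#' @return A ggplot.
#' @export
#' @importFrom rlang .data
plot_rarefaction <- function(x, depths = NULL) {
  rows <- do.call(rbind, lapply(x$thresholds, function(t) {
    v <- otu_abundances(x, t)
    dd <- depths %||% unique(round(seq(0, sum(v), length.out = 21)))
    tibble(threshold = factor(t), depth = dd, richness = rarefaction(v, dd))
  }))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$depth, y = .data$richness,
                                     colour = .data$threshold)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reads sampled", y = "expected OTUs",
                  title = "Rarefaction curves")
}
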