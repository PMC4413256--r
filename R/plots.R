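#' Manhattan plot of an association scan
#'
#' @param scan An `assoc_scan` (or tibble with `chrom`, `pos`, `p`).
#' @param threshold Optional -log10 p threshold line; defaults to the
#'   scan's Bonferroni threshold when available.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, threshold = NULL) {
  threshold <- threshold %||% attr(scan, "bonferroni")
  d <- dplyr::filter(tibble::as_tibble(scan), !is.na(.data$p))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                       colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  p
}

#' Reaction-norm plot of genome-wide context averages
#'
#' One line per accession connecting its genome-wide methylation level in
#' the two environments, faceted by context.
#'
#' @param ctx_avg Output of [context_averages()].
#' @return A ggplot object.
#' @export
plot_reaction_norms <- function(ctx_avg) {
  ggplot2::ggplot(ctx_avg,
                  ggplot2::aes(x = .data$env, y = .data$level,
                               group = .data$accession)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$context), scales = "free_y") +
    ggplot2::labs(x = "growth environment", y = "methylation level") +
    ggplot2::theme_minimal()
}

#' @describeIn hk_scan LOD curve with the genome-wide threshold.
#' @param object An `hk_scan`.
#' @param ... Unused.
#' @export
autoplot.hk_scan <- function(object, ...) {
  ggplot2::ggplot(object$lod, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
}

#' Stacked variance-decomposition plot over explained-variance bins
#'
#' @param bins Output of [bin_by_total_variance()].
#' @return A ggplot object.
#' @export
plot_varcomp_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_mid, y = .data$mean_fraction,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "stack", width = 0.08) +
    ggplot2::labs(x = "total variance explained", y = "mean fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
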