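#' Plot the architecture of a processed precursor
#'
#' Draws the precursor protein as a horizontal track with the signal peptide,
#' mature peptides (amidated ones marked) and the cleavage-site linkers
#' between them, in protein coordinates.
#'
#' @param x An `np_peptides` result from [process_precursor()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_precursor_map <- function(x, title = NULL) {
  stopifnot(inherits(x, "np_peptides"))
  sig <- attr(x, "signal")
  protein <- attr(x, "protein")
  feats <- bind_rows(
    if (sig$length_aa > 0)
      tibble(start = 1, end = sig$length_aa, kind = "signal peptide"),
    tibble(start = x$start_aa, end = x$end_aa,
           kind = ifelse(x$amidated, "mature peptide (amidated)", "mature peptide"))
  )
  ggplot2::ggplot(feats) +
    ggplot2::geom_segment(ggplot2::aes(x = 0.5, xend = nchar(protein) + 0.5,
                                       y = 0, yend = 0),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                                    ymin = -0.35, ymax = 0.35, fill = .data$kind),
                       colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      "signal peptide" = "#d95f5f",
      "mature peptide" = "#7fbf7f",
      "mature peptide (amidated)" = "#4f9fdf"
    )) +
    ggplot2::labs(x = "residue", y = NULL, fill = NULL, title = title) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(-1, 1)) +
    ggplot2::theme_minimal()
}

#' Plot an expression contrast
#'
#' Brain versus eyestalk mean RPKM on log10 axes, coloured by the
#' significance call of the tissue contrast.
#'
#' @param object An `np_contrast` from [tissue_contrast()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_contrast
#' @export
autoplot.np_contrast <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$brain_mean + 0.01,
                                   y = .data$eyestalk_mean + 0.01,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey40")) +
    ggplot2::labs(x = "brain mean RPKM (+0.01)", y = "eyestalk mean RPKM (+0.01)",
                  colour = sprintf("p < %g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Plot a neighbor-joining tree
#'
#' @param object An `np_njtree` from [nj_tree()].
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly (plots as a side effect).
#' @method autoplot np_njtree
#' @export
autoplot.np_njtree <- function(object, ...) {
  ape::plot.phylo(object$tree, ...)
  invisible(object)
}
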