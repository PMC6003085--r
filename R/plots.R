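#' Plot a linkage map
#'
#' One vertical bar per linkage group with markers as ticks at their Kosambi
#' positions.
#'
#' @param object A `gbs_map` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_map <- function(object, ...) {
  d <- object$map
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_id, y = .data$position_cm)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$group_id),
                       linewidth = 2, colour = "grey85") +
    ggplot2::geom_point(shape = 95, size = 5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (cM, Kosambi)",
                  title = "GBS linkage map") +
    ggplot2::theme_minimal()
}

#' Plot progenitor presence/absence along linkage groups
#'
#' The presence scatter used to assign subgenomes: informative tags at y = 2
#' (present in the diploid progenitor) or y = 0 (absent), by map position,
#' one facet per linkage group, with detected breakpoints as dashed lines.
#'
#' @param object A `gbs_subgenome` object ([assign_subgenome()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_subgenome <- function(object, ...) {
  sc <- subgenome_scatter(object)
  bp <- tidyr::unnest(
    tibble(group_id = object$group_id, breakpoint = object$breakpoints),
    "breakpoint")
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$position_cm, y = .data$y)) +
    ggplot2::geom_jitter(width = 0, height = 0.08, size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~group_id, scales = "free_x") +
    ggplot2::scale_y_continuous(breaks = c(0, 2), limits = c(-0.5, 2.5)) +
    ggplot2::labs(x = "position (cM)", y = "progenitor presence class",
                  title = "Progenitor tag presence by linkage group") +
    ggplot2::theme_minimal()
  if (nrow(bp)) {
    p <- p + ggplot2::geom_vline(data = bp,
                                 ggplot2::aes(xintercept = .data$breakpoint),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot genotype-code composition per sample
#'
#' Stacked counts of codes per sample — a quick QC view of a genotype matrix.
#'
#' @param geno Wide genotype matrix.
#' @return A ggplot.
#' @export
plot_geno_composition <- function(geno) {
  scols <- geno_samples(geno)
  long <- tidyr::pivot_longer(geno[, scols], cols = dplyr::all_of(scols),
                              names_to = "sample_id", values_to = "code")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, fill = .data$code)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "markers", fill = "code") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}
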