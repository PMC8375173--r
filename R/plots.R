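# ggplot2 views of the survey results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot subset composition of a family summary
#'
#' @param object A `family_summary` from [summarize_family()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.family_summary <- function(object, ...) {
  ggplot2::ggplot(object$subsets,
                  ggplot2::aes(x = stats::reorder(.data$subset, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proteins",
                  title = "C2H2-ZF subset composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Domain-architecture map of selected proteins
#'
#' Draws each protein as a horizontal line with its fingers as typed
#' segments — the usual gene-family architecture panel.
#'
#' @param domains Domain tibble from [scan_domains()].
#' @param proteins Protein tibble (for sequence lengths).
#' @param ids Optional subset of protein ids to draw (default: up to 20).
#' @return A ggplot.
#' @export
plot_domain_map <- function(domains, proteins, ids = NULL) {
  if (is.null(ids)) ids <- utils::head(unique(domains$protein_id), 20)
  prot <- proteins |>
    dplyr::filter(.data$id %in% ids) |>
    dplyr::mutate(len = nchar(.data$sequence),
                  y = factor(.data$id, levels = rev(ids)))
  dom <- domains |>
    dplyr::filter(.data$protein_id %in% ids) |>
    dplyr::mutate(y = factor(.data$protein_id, levels = rev(ids)),
                  type = collapse_type(.data$dtype))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = prot,
                          ggplot2::aes(x = 1, xend = .data$len,
                                       y = .data$y, yend = .data$y),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_segment(data = dom,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$type),
                          linewidth = 3) +
    ggplot2::labs(x = "residue", y = NULL, colour = "finger type") +
    ggplot2::theme_minimal()
}

#' Expression heatmap of clustered genes
#'
#' log2(TPM + 1) tile map with genes ordered by expression group.
#'
#' @param tpm TPM tibble.
#' @param clusters Optional `expression_clusters` object used to order
#'   genes by group.
#' @return A ggplot.
#' @export
plot_expression_heatmap <- function(tpm, clusters = NULL) {
  long <- tpm_long(tpm)
  if (!is.null(clusters)) {
    ord <- tidy(clusters) |> dplyr::arrange(.data$group, .data$gene_id)
    long$gene_id <- factor(long$gene_id, levels = rev(ord$gene_id))
  }
  long$stage <- factor(long$stage, levels = unique(long$stage))
  ggplot2::ggplot(long, ggplot2::aes(.data$stage, .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(TPM+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
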