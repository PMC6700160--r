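#' QQ plot of NPC global p-values
#'
#' Observed versus expected -log10 global p-values; under a global null the
#' points follow the identity line, and the plateau at `-log10(1/(B+1))`
#' shows the permutation granularity.
#'
#' @param object An `npc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npc_result
#' @export
autoplot.npc_result <- function(object, ...) {
  tab <- object$table |>
    dplyr::arrange(.data$global_p) |>
    dplyr::mutate(expected = (dplyr::row_number() - 0.5) / dplyr::n())
  ggplot2::ggplot(tab, ggplot2::aes(-log10(.data$expected),
                                    -log10(.data$global_p))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = expression(-log[10] ~ "expected p"),
                  y = expression(-log[10] ~ "global p"),
                  title = sprintf("NPC global p-values (B = %d)", object$B)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of per-contrast t statistics
#'
#' @param t_stats Output of [contrast_t_statistics()] (optionally row-bound
#'   over datasets/contrasts; facets follow the available columns).
#' @return A ggplot object.
#' @export
plot_volcano <- function(t_stats) {
  p <- ggplot2::ggplot(t_stats,
                       ggplot2::aes(.data$estimate,
                                    -log10(.data$p.value))) +
    ggplot2::geom_point(size = 0.7, alpha = 0.5) +
    ggplot2::labs(x = "effect (log scale)",
                  y = expression(-log[10] ~ "p")) +
    ggplot2::theme_minimal()
  facets <- intersect(c("dataset_id", "contrast"), names(t_stats))
  if (length(facets)) {
    p <- p + ggplot2::facet_grid(
      rows = if ("dataset_id" %in% facets) ggplot2::vars(.data$dataset_id),
      cols = if ("contrast" %in% facets) ggplot2::vars(.data$contrast))
  }
  p
}

#' Scatter plot of one gene-probe expression/methylation pair
#'
#' One panel per dataset; samples shared between the two modalities (matched
#' by individual) are shown, coloured by disease group.
#'
#' @param gene_id,probe_id Feature ids.
#' @param expression,methylation Named lists of [omics_dataset()] objects.
#' @param design Design tibble.
#' @return A ggplot object.
#' @export
plot_pair_correlation <- function(gene_id, probe_id, expression, methylation,
                                  design) {
  dataset_ids <- intersect(names(expression), names(methylation))
  dat <- purrr::map(dataset_ids, function(d) {
    dd <- dplyr::filter(design, .data$dataset_id == d)
    keep <- dd$sample_id %in% colnames(expression[[d]]$values) &
      dd$sample_id %in% colnames(methylation[[d]]$values)
    dd <- dd[keep, ]
    tibble::tibble(dataset_id = d, group = dd$group,
                   expression = expression[[d]]$values[gene_id, dd$sample_id],
                   methylation = methylation[[d]]$values[probe_id,
                                                         dd$sample_id])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(.data$methylation, .data$expression,
                                    colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~dataset_id, scales = "free") +
    ggplot2::labs(title = paste(gene_id, probe_id, sep = " - "),
                  x = "methylation (beta)", y = "expression (log2 CPM)") +
    ggplot2::theme_minimal()
}
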