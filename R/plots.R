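# ggplot2 graphics for the result objects.

#' Plot the running-sum enrichment curve for one gene set
#'
#' The running sum over the ranked gene list, with member-gene positions shown
#' as a rug. The peak is the enrichment score.
#'
#' @param scores A `gene_scores` tibble.
#' @param members Character vector of member gene ids.
#' @param weight_exponent Score exponent `p` (default 1).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(scores, members, weight_exponent = 1) {
  es <- enrichment_score(scores, members, weight_exponent = weight_exponent)
  scores <- dplyr::arrange(tibble::as_tibble(scores),
                           dplyr::desc(score), gene_id)
  df <- tibble::tibble(
    rank = seq_along(es$hit_curve),
    running_sum = es$hit_curve,
    hit = scores$gene_id %in% members
  )
  ggplot2::ggplot(df, ggplot2::aes(x = rank, y = running_sum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b",
                      colour = "#d95f02", alpha = 0.7) +
    ggplot2::labs(
      x = "gene rank", y = "running enrichment sum",
      title = sprintf("ES = %.3f (%d member genes)", es$es, es$n_overlap)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a gsea_result
#'
#' NES against -log10 empirical p per chemical, coloured by significance.
#'
#' @param object A `gsea_result` from [run_gsea()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = nes, y = -log10(p_empirical),
                                   colour = significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#d95f02")) +
    ggplot2::labs(x = "normalized enrichment score (NES)",
                  y = expression(-log[10] ~ "empirical p"),
                  colour = "significant",
                  title = if (nrow(df) > 0) df$stream[1] else NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot an integration_report
#'
#' Bar chart of the per-region chemical counts (per-tissue breakdowns, the
#' per-disease common sets and the cross-disease common set).
#'
#' @param object An `integration_report` from [build_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.integration_report <- function(object, ...) {
  df <- object$counts
  df$label <- paste(df$disease, df$region, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(label, n), y = n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "chemicals",
                  title = "significant-chemical intersection counts") +
    ggplot2::theme_minimal()
}
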