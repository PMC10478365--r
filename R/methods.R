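#' Tidy a priority report into long form
#'
#' @param x A `priority_report`.
#' @param ... Unused.
#' @return A tibble with one row per gene and criterion (`gene`,
#'   `criterion`, `rank`, `average_rank`).
#' @method tidy priority_report
#' @export
tidy.priority_report <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      dplyr::starts_with("rank"),
      names_to = "criterion", names_prefix = "rank",
      values_to = "rank"
    ) |>
    mutate(criterion = as.integer(.data$criterion)) |>
    select("gene", "criterion", "rank", "average_rank")
}

#' One-row summary of a priority report
#'
#' @param x A `priority_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of candidates, best/median average
#'   rank and the top gene.
#' @method glance priority_report
#' @export
glance.priority_report <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    top_gene = x$gene[1],
    min_average_rank = min(x$average_rank),
    median_average_rank = stats::median(x$average_rank)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `comorank_run`.
#' @param ... Unused.
#' @return A one-row tibble of run-level counts.
#' @method glance comorank_run
#' @export
glance.comorank_run <- function(x, ...) {
  tibble(
    n_candidates = length(x$candidates),
    n_edges_complete = nrow(x$complete_network$edges),
    n_edges_regulatory = nrow(x$regulatory_network$edges),
    n_enriched_complete = sum(x$enrichment_complete$enriched),
    n_enriched_regulatory = sum(x$enrichment_regulatory$enriched),
    n_specific_genes = sum(x$specificity$specific),
    n_qualifying_snps = nrow(x$qualifying_snps),
    top_gene = x$report$gene[1]
  )
}

#' Heatmap of per-criterion ranks for the top genes
#'
#' Tiles genes (best average rank at the top) against the ten criteria,
#' filled by rank, so the evidence profile behind each candidate is
#' visible at a glance.
#'
#' @param object A `priority_report`.
#' @param top_n Number of top genes to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.priority_report <- function(object, top_n = 20, ...) {
  top <- head(as_tibble(object), top_n)
  long <- tidy.priority_report(new_priority_report(top))
  long$gene <- factor(long$gene, levels = rev(top$gene))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$criterion, levels = 1:10),
    y = .data$gene, fill = .data$rank
  )) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "criterion", y = NULL, fill = "rank",
      title = sprintf("Per-criterion ranks, top %d genes", nrow(top))
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of enriched GO biological processes
#'
#' @param object An `enrichment_tbl` from [enrich_processes()].
#' @param top_n Number of processes to show (default 20, by q-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_tbl
#' @export
autoplot.enrichment_tbl <- function(object, top_n = 20, ...) {
  top <- head(arrange(as_tibble(object), .data$q_value), top_n)
  top$label <- ifelse(
    is.na(top$process_name), top$process_id,
    paste(top$process_id, top$process_name)
  )
  ggplot2::ggplot(top, ggplot2::aes(
    x = -log10(.data$q_value),
    y = stats::reorder(.data$label, -.data$q_value),
    size = .data$k, color = .data$enriched
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(-log[10] ~ "FDR"), y = NULL,
      size = "query genes", color = "enriched"
    ) +
    ggplot2::theme_minimal()
}

#' Centrality scatter with hub cutoffs
#'
#' Betweenness against neighborhood cohesion, point size by degree,
#' with the hub cutoffs drawn as reference lines.
#'
#' @param object A `centrality_tbl` from [compute_centralities()].
#' @param bc_min,cc_min Hub cutoffs drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot centrality_tbl
#' @export
autoplot.centrality_tbl <- function(object, bc_min = 0.005, cc_min = 0.2, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$bc, y = .data$cc, size = .data$degree_raw
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = bc_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cc_min, linetype = "dashed") +
    ggplot2::labs(
      x = "betweenness centrality", y = "neighborhood cohesion (CC)",
      size = "degree"
    ) +
    ggplot2::theme_minimal()
}
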