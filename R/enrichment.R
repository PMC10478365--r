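#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the sorted p-values, clipped
#' to 1 and returned in the input order. Thin wrapper over
#' `stats::p.adjust(method = "BH")` with input validation.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' GO biological-process over-representation test
#'
#' One-sided hypergeometric test per process: with a universe of `N`
#' annotated genes, `K` of them annotated to the process, and a query of
#' `n` genes of which `k` carry the annotation, the p-value is the upper
#' tail \eqn{P(X \ge k)}. An optional EASE-style offset tests
#' \eqn{P(X \ge k - \mathrm{offset})} for a more conservative score.
#' Adjustment is Benjamini-Hochberg over all processes with at least one
#' query gene.
#'
#' @param query Character vector of gene symbols. Genes outside the
#'   annotation universe are dropped with a warning.
#' @param annotations Annotation tibble (`process_id`, `process_name`,
#'   `gene`) as from [read_go_inputs()].
#' @param alpha Enrichment threshold on the adjusted p-value (default
#'   0.01).
#' @param ease_offset Nonnegative integer subtracted from `k` before the
#'   tail is computed (default 0, the plain hypergeometric).
#' @return A tibble (`process_id`, `process_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `enriched`, `members`) with one row per
#'   process overlapping the query, sorted by p-value; class
#'   `enrichment_tbl`.
#' @export
enrich_processes <- function(query, annotations, alpha = 0.01, ease_offset = 0L) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  assert_scalar_number(ease_offset, "ease_offset", lower = 0)
  annotations <- as_tibble(annotations)
  universe <- unique(sym_key(annotations$gene))
  query_keys <- unique(sym_key(query))
  dropped <- setdiff(query_keys, universe)
  if (length(dropped) > 0L) {
    warn(sprintf("%d query gene(s) outside the annotation universe dropped.", length(dropped)))
    query_keys <- setdiff(query_keys, dropped)
  }
  if (length(query_keys) == 0L) {
    abort("Query is empty after restriction to the annotation universe.")
  }
  n_universe <- length(universe)
  n_query <- length(query_keys)

  per_process <- annotations |>
    mutate(gene_key = sym_key(.data$gene)) |>
    distinct(.data$process_id, .data$process_name, .data$gene_key, .keep_all = TRUE) |>
    group_by(.data$process_id) |>
    summarise(
      process_name = .data$process_name[1],
      K = dplyr::n(),
      members = list(sort(unique(.data$gene[.data$gene_key %in% query_keys]))),
      k = length(members[[1]]),
      .groups = "drop"
    ) |>
    filter(.data$k >= 1L)

  if (nrow(per_process) == 0L) {
    out <- tibble(
      process_id = character(0), process_name = character(0),
      k = integer(0), K = integer(0), n = integer(0), N = integer(0),
      p_value = numeric(0), q_value = numeric(0), enriched = logical(0),
      members = list()
    )
    class(out) <- c("enrichment_tbl", class(out))
    return(out)
  }

  k_eff <- pmax(per_process$k - ease_offset, 0L)
  # upper tail P(X >= k): phyper with lower.tail = FALSE gives P(X > q)
  p <- phyper(k_eff - 1L, per_process$K, n_universe - per_process$K,
    n_query,
    lower.tail = FALSE
  )
  out <- per_process |>
    mutate(
      n = n_query, N = n_universe,
      p_value = pmin(pmax(p, 0), 1),
      q_value = bh_fdr(.data$p_value),
      enriched = .data$q_value < alpha
    ) |>
    select(
      "process_id", "process_name", "k", "K", "n", "N",
      "p_value", "q_value", "enriched", "members"
    ) |>
    arrange(.data$p_value, .data$process_id)
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' Write an enrichment table as TSV
#'
#' @param enrichment An `enrichment_tbl` from [enrich_processes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  out <- enrichment |>
    mutate(members = purrr::map_chr(.data$members, paste, collapse = ";"))
  readr::write_tsv(as_tibble(out), path)
  invisible(path)
}

#' Per-gene counts of enriched processes (criterion 4)
#'
#' For each candidate gene, counts the enriched GO biological processes
#' of the complete comorbidity network that include the gene (`n1`), the
#' analogous count for the regulatory network (`n2`), and their sum
#' `n_total = n1 + n2`, the quantity ranked by criterion 4. Genes absent
#' from every enriched process get 0 and stay in the output.
#'
#' @param enriched_complete,enriched_regulatory Enrichment tables from
#'   [enrich_processes()]; only rows flagged `enriched` are counted.
#' @param genes Candidate gene symbols.
#' @return A tibble `gene`, `n1`, `n2`, `n_total`.
#' @export
criterion4_counts <- function(enriched_complete, enriched_regulatory, genes) {
  count_in <- function(enr) {
    members <- filter(as_tibble(enr), .data$enriched)$members
    keys <- sym_key(unlist(members))
    vapply(sym_key(genes), function(g) sum(keys == g), integer(1))
  }
  n1 <- count_in(enriched_complete)
  n2 <- count_in(enriched_regulatory)
  tibble(
    gene = genes,
    n1 = unname(n1),
    n2 = unname(n2),
    n_total = unname(n1 + n2)
  )
}
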