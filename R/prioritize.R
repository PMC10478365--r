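#' Rank candidate genes by a score
#'
#' The best score receives rank 1; ties share the average of the ranks
#' they span (so rank sums are conserved); candidates without a score
#' receive the worst rank `N = length(candidates)`, the same "absent"
#' value the binary SNP criteria use.
#'
#' @param scores Named numeric vector or two-column data frame
#'   (`gene`, `score`).
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param candidates Candidate gene symbols.
#' @return Named numeric vector of ranks over `candidates`.
#' @export
#' @examples
#' rank_by_score(c(A = 0.9, B = 0.5, C = 0.5, D = 0.1),
#'   "higher_is_better", c("A", "B", "C", "D"))
rank_by_score <- function(scores, direction = c("higher_is_better", "lower_is_better"),
                          candidates) {
  direction <- match.arg(direction)
  if (length(candidates) == 0L) abort("Candidate list is empty.")
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$gene)
  }
  n <- length(candidates)
  idx <- match(sym_key(candidates), sym_key(names(scores)))
  s <- unname(scores[idx])
  if (direction == "higher_is_better") s <- -s
  have <- !is.na(s)
  ranks <- rep(as.numeric(n), n)
  ranks[have] <- rank(s[have], ties.method = "average")
  setNames(ranks, candidates)
}

#' Assemble the gene-by-criterion rank matrix
#'
#' Converts every criterion's scores into ranks over the candidate
#' list:
#' * criteria 1-3 from external prioritizer tables, each ranked in its
#'   fixed direction (relevance score and average score descending,
#'   p-value ascending); a missing table leaves the column at the worst
#'   rank `N` and is recorded in the provenance;
#' * criterion 4 descending by `n_total`, the gene's participation in
#'   enriched processes of the complete plus regulatory networks;
#' * criteria 5 and 6 descending by the unweighted mean of the
#'   normalized degree, betweenness and neighborhood-cohesion
#'   centralities in the complete and regulatory networks respectively
#'   (entities absent from a network score 0 there);
#' * criterion 7 by the specificity ordering (positively associated
#'   genes by ascending adjusted p, then the rest alphabetically);
#' * criteria 8-10 passed through from [binary_snp_criterion()].
#'
#' @param external List of up to three `external_scores` tables (may
#'   contain `NULL` entries for absent criteria).
#' @param c4 Criterion-4 counts from [criterion4_counts()].
#' @param centralities_complete,centralities_regulatory Centrality
#'   tables from [compute_centralities()].
#' @param c7 Specificity table from [criterion7_scores()].
#' @param c8,c9,c10 Binary rank tables from [binary_snp_criterion()].
#' @param candidates Candidate gene symbols (list X).
#' @return A tibble (`gene`, `rank1`..`rank10`) with a `provenance`
#'   attribute, class `rank_matrix`.
#' @export
assemble_rank_matrix <- function(external, c4,
                                 centralities_complete, centralities_regulatory,
                                 c7, c8, c9, c10, candidates) {
  if (length(candidates) == 0L) abort("Candidate list is empty.")
  n <- length(candidates)
  worst <- setNames(rep(as.numeric(n), n), candidates)
  provenance <- character(10)

  ranks <- list()
  for (cid in 1:3) {
    tab <- purrr::detect(external, function(t) {
      !is.null(t) && identical(attr(t, "criterion_id"), as.integer(cid))
    })
    if (is.null(tab)) {
      ranks[[cid]] <- worst
      provenance[cid] <- "missing (worst rank)"
    } else {
      ranks[[cid]] <- rank_by_score(tab, attr(tab, "direction"), candidates)
      provenance[cid] <- "external"
    }
  }

  ranks[[4]] <- rank_by_score(
    setNames(as.numeric(c4$n_total), c4$gene), "higher_is_better", candidates
  )
  provenance[4] <- "computed"

  centrality_score <- function(cent) {
    cent <- as_tibble(cent)
    setNames((cent$dc + cent$bc + cent$cc) / 3, cent$entity)
  }
  for (cid in 5:6) {
    cent <- if (cid == 5L) centralities_complete else centralities_regulatory
    sc <- centrality_score(cent)
    # candidates absent from the network get the worst centrality, 0
    full <- setNames(rep(0, n), candidates)
    idx <- match(sym_key(names(sc)), sym_key(candidates))
    full[idx[!is.na(idx)]] <- sc[!is.na(idx)]
    ranks[[cid]] <- rank_by_score(full, "higher_is_better", candidates)
    provenance[cid] <- "computed"
  }

  r7 <- criterion7_rank(c7)
  idx7 <- match(sym_key(candidates), sym_key(names(r7)))
  if (any(is.na(idx7))) abort("Criterion 7 scores missing for some candidates.")
  ranks[[7]] <- setNames(unname(r7[idx7]), candidates)
  provenance[7] <- "computed"

  for (cid in 8:10) {
    tab <- list(c8, c9, c10)[[cid - 7L]]
    idx <- match(sym_key(candidates), sym_key(tab$gene))
    if (any(is.na(idx)) || nrow(tab) != n) {
      abort(sprintf("Criterion %d ranks do not cover the candidate list.", cid))
    }
    ranks[[cid]] <- setNames(tab$rank[idx], candidates)
    provenance[cid] <- "computed"
  }

  out <- tibble(gene = candidates)
  for (cid in 1:10) out[[paste0("rank", cid)]] <- unname(ranks[[cid]])
  attr(out, "provenance") <- setNames(provenance, paste0("rank", 1:10))
  class(out) <- c("rank_matrix", class(out))
  out
}

#' Aggregate criterion ranks into the final priority table
#'
#' The final score of a gene is the arithmetic mean of its ten
#' criterion ranks; rows are sorted ascending by average rank (lower
#' average = higher priority), alphabetically within ties.
#'
#' @param matrix A `rank_matrix` from [assemble_rank_matrix()].
#' @return A tibble (`gene`, `rank1`..`rank10`, `average_rank`), class
#'   `priority_report`.
#' @export
aggregate_average_rank <- function(matrix) {
  rank_cols <- paste0("rank", 1:10)
  if (!all(rank_cols %in% names(matrix))) {
    abort("Rank matrix must contain columns rank1..rank10.")
  }
  if (anyNA(matrix[rank_cols])) abort("Rank matrix is incomplete (NA ranks).")
  out <- as_tibble(matrix) |>
    mutate(average_rank = rowMeans(across(dplyr::all_of(rank_cols)))) |>
    arrange(.data$average_rank, .data$gene)
  new_priority_report(out[c("gene", rank_cols, "average_rank")])
}

new_priority_report <- function(x) {
  out <- as_tibble(x)
  attr(out, "provenance") <- NULL
  class(out) <- setdiff(c("priority_report", class(out)), "rank_matrix")
  out
}
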