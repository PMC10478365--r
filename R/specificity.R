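#' Split GO processes into disease-shared test set and control set
#'
#' The test set contains the biological processes linked to BOTH
#' diseases; the control set contains every other annotated process.
#' Processes linked to a disease but missing from the annotations are
#' excluded with a warning (the annotation file is the universe).
#'
#' @param links Disease-process link tibble (`disease`, `process_id`).
#' @param disease_a,disease_b Disease names.
#' @param annotations Annotation tibble (`process_id`, `gene`, ...).
#' @return A list with character vectors `test` and `control`
#'   (disjoint; their union is the annotated process set).
#' @export
build_test_control_sets <- function(links, disease_a, disease_b, annotations) {
  links <- as_tibble(links)
  for (d in c(disease_a, disease_b)) {
    if (!d %in% links$disease) {
      abort(sprintf("Disease '%s' absent from the process links.", d))
    }
  }
  annotated <- unique(annotations$process_id)
  linked_a <- unique(links$process_id[links$disease == disease_a])
  linked_b <- unique(links$process_id[links$disease == disease_b])
  shared <- intersect(linked_a, linked_b)
  outside <- setdiff(shared, annotated)
  if (length(outside) > 0L) {
    warn(sprintf(
      "%d disease-shared process(es) absent from the annotations were excluded.",
      length(outside)
    ))
  }
  test <- intersect(shared, annotated)
  if (length(test) == 0L) {
    abort("No annotated process is linked to both diseases; the specificity criterion is undefined.")
  }
  list(test = sort(test), control = sort(setdiff(annotated, test)))
}

#' Welch's unequal-variance t-test
#'
#' The two-sample t statistic with unpooled variances,
#' \eqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}}, the
#' Welch-Satterthwaite degrees of freedom, and the two-sided p-value
#' from the t distribution.
#'
#' @param sample_x,sample_y Numeric vectors with at least 2 values each.
#' @return A list with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(1, 1, 0, 1), c(0, 1, 0, 0))
welch_t <- function(sample_x, sample_y) {
  nx <- length(sample_x)
  ny <- length(sample_y)
  if (nx < 2L || ny < 2L) abort("Both samples need at least 2 values.")
  vx <- stats::var(sample_x)
  vy <- stats::var(sample_y)
  if (vx == 0 && vy == 0) {
    abort("Both samples have zero variance; the Welch statistic is undefined.")
  }
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(sample_x) - mean(sample_y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(t = t_stat, df = df, p = p)
}

#' Per-gene specificity for disease-shared processes (criterion 7)
#'
#' For each gene, a 0/1 membership vector is formed over the test
#' processes (linked to both diseases) and over the control processes
#' (all others); Welch's t-test compares the two vectors, so a positive
#' statistic means the gene is annotated to disease-shared processes
#' more often than to the background. P-values are BH-adjusted across
#' genes; a gene annotated to nothing (both variances zero) is flagged
#' degenerate with p = 1.
#'
#' @param genes Candidate gene symbols.
#' @param annotations Annotation tibble (`process_id`, `gene`, ...).
#' @param sets Test/control split from [build_test_control_sets()].
#' @param alpha Threshold on the adjusted p-value for the `specific`
#'   flag (default 0.05).
#' @return A tibble (`gene`, `t_stat`, `df`, `p_value`, `q_value`,
#'   `mean_test`, `mean_control`, `degenerate`, `specific`), class
#'   `specificity_tbl`.
#' @export
criterion7_scores <- function(genes, annotations, sets, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (length(sets$test) < 2L || length(sets$control) < 2L) {
    abort("Both the test and control process sets need at least 2 processes.")
  }
  ann <- as_tibble(annotations) |>
    mutate(gene_key = sym_key(.data$gene)) |>
    distinct(.data$process_id, .data$gene_key)

  one_gene <- function(g) {
    key <- sym_key(g)
    annotated_to <- ann$process_id[ann$gene_key == key]
    x <- as.numeric(sets$test %in% annotated_to)
    y <- as.numeric(sets$control %in% annotated_to)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      # no variance on either side: uninformative (equal means, e.g. a
      # gene with no annotations) unless the separation is perfect, in
      # which case the statistic diverges and the evidence is maximal
      if (mean(x) == mean(y)) {
        tibble(
          gene = g, t_stat = 0, df = NA_real_, p_value = 1,
          mean_test = mean(x), mean_control = mean(y), degenerate = TRUE
        )
      } else {
        tibble(
          gene = g, t_stat = sign(mean(x) - mean(y)) * Inf,
          df = NA_real_, p_value = 0,
          mean_test = mean(x), mean_control = mean(y), degenerate = FALSE
        )
      }
    } else {
      w <- welch_t(x, y)
      tibble(
        gene = g, t_stat = w$t, df = w$df, p_value = w$p,
        mean_test = mean(x), mean_control = mean(y), degenerate = FALSE
      )
    }
  }
  out <- bind_rows(purrr::map(genes, one_gene)) |>
    mutate(
      q_value = bh_fdr(.data$p_value),
      specific = !.data$degenerate & .data$t_stat > 0 & .data$q_value < alpha
    ) |>
    select(
      "gene", "t_stat", "df", "p_value", "q_value",
      "mean_test", "mean_control", "degenerate", "specific"
    )
  class(out) <- c("specificity_tbl", class(out))
  out
}

# ranking order for criterion 7: genes positively and non-degenerately
# associated with the test set first, ascending adjusted p; the rest
# after them, alphabetically
criterion7_rank <- function(scores) {
  scores <- as_tibble(scores)
  pos <- !scores$degenerate & scores$t_stat > 0
  n_pos <- sum(pos)
  ranks <- numeric(nrow(scores))
  if (n_pos > 0L) {
    ranks[pos] <- rank(scores$q_value[pos], ties.method = "average")
  }
  if (any(!pos)) {
    ranks[!pos] <- n_pos + rank(scores$gene[!pos], ties.method = "first")
  }
  setNames(ranks, scores$gene)
}
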