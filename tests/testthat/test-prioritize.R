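test_that("rank_by_score handles direction, ties and missing scores", {
  cand <- c("A", "B", "C", "D")
  r <- rank_by_score(c(A = 0.9, B = 0.5, C = 0.5, D = 0.1), "higher_is_better", cand)
  expect_equal(unname(r), c(1, 2.5, 2.5, 4))

  p <- rank_by_score(c(A = 1e-5, B = 0.3), "lower_is_better", c("A", "B"))
  expect_equal(unname(p), c(1, 2))

  miss <- rank_by_score(c(A = 1, B = 2, C = 3), "higher_is_better", c("A", "B", "C", "E"))
  expect_equal(unname(miss["E"]), 4)

  expect_error(rank_by_score(c(A = 1), "higher_is_better", character(0)), "empty")
})

# minimal consistent inputs for the assembly step over a candidate set
assembly_inputs <- function(candidates, seed = 1) {
  set.seed(seed)
  n <- length(candidates)
  cent <- function() {
    out <- tibble::tibble(
      entity = candidates,
      degree_raw = sample(0:5, n, replace = TRUE),
      dc = runif(n), bc = runif(n), cc = runif(n)
    )
    class(out) <- c("centrality_tbl", class(out))
    out
  }
  sets <- list(
    test = sprintf("GO:%07d", 1:4),
    control = sprintf("GO:%07d", 5:12)
  )
  ann <- dplyr::bind_rows(lapply(c(sets$test, sets$control), function(p) {
    tibble::tibble(
      process_id = p, process_name = NA_character_,
      gene = sample(candidates, sample(2:n, 1))
    )
  }))
  binary <- function() tibble::tibble(
    gene = candidates,
    rank = sample(c(1, n), n, replace = TRUE),
    evidence_snp_ids = replicate(n, character(0), simplify = FALSE)
  )
  list(
    external = list(
      external_scores(tibble::tibble(gene = candidates, score = runif(n)), 1),
      external_scores(tibble::tibble(gene = candidates, score = runif(n)), 2),
      external_scores(tibble::tibble(gene = candidates, score = runif(n)), 3)
    ),
    c4 = tibble::tibble(
      gene = candidates, n1 = sample(0:9, n, TRUE), n2 = sample(0:9, n, TRUE)
    ) |> dplyr::mutate(n_total = n1 + n2),
    cent_complete = cent(), cent_regulatory = cent(),
    c7 = criterion7_scores(candidates, ann, sets),
    c8 = binary(), c9 = binary(), c10 = binary()
  )
}

assemble_from <- function(inp, candidates) {
  assemble_rank_matrix(
    inp$external, inp$c4, inp$cent_complete, inp$cent_regulatory,
    inp$c7, inp$c8, inp$c9, inp$c10, candidates
  )
}

test_that("rank matrix assembly ranks each criterion in its declared direction", {
  candidates <- c("A", "B", "C", "D", "E")
  inp <- assembly_inputs(candidates, seed = 7)
  inp$c4$n_total <- c(10, 1, 2, 3, 4)
  inp$cent_complete$dc <- c(1, 0.1, 0.2, 0.3, 0.4)
  inp$cent_complete$bc <- c(1, 0.1, 0.2, 0.3, 0.4)
  inp$cent_complete$cc <- c(1, 0.1, 0.2, 0.3, 0.4)
  mat <- assemble_from(inp, candidates)
  expect_equal(mat$rank4[mat$gene == "A"], 1)
  expect_equal(mat$rank5[mat$gene == "A"], 1)
  expect_equal(mat$rank9, inp$c9$rank)
  expect_true(all(as.matrix(mat[paste0("rank", 1:10)]) >= 1))
  expect_true(all(as.matrix(mat[paste0("rank", 1:10)]) <= 5))

  # a missing external table yields the worst rank and is recorded
  mat2 <- assemble_rank_matrix(
    inp$external[1:2], inp$c4, inp$cent_complete, inp$cent_regulatory,
    inp$c7, inp$c8, inp$c9, inp$c10, candidates
  )
  expect_true(all(mat2$rank3 == 5))
  expect_match(attr(mat2, "provenance")[["rank3"]], "missing")
})

test_that("entities absent from the regulatory network rank worst under criterion 6", {
  candidates <- c("A", "B", "C")
  inp <- assembly_inputs(candidates, seed = 3)
  inp$cent_regulatory <- inp$cent_regulatory[inp$cent_regulatory$entity != "B", ]
  inp$cent_regulatory$dc <- c(0.9, 0.8)
  inp$cent_regulatory$bc <- c(0.9, 0.8)
  inp$cent_regulatory$cc <- c(0.9, 0.8)
  mat <- assemble_from(inp, candidates)
  expect_equal(mat$rank6[mat$gene == "B"], 3)
})

test_that("average-rank aggregation sorts ascending with alphabetical ties", {
  mat <- tibble::tibble(gene = c("X", "Y"))
  for (i in 1:10) mat[[paste0("rank", i)]] <- c(1, i)
  rep <- aggregate_average_rank(mat)
  expect_equal(rep$average_rank[rep$gene == "X"], 1)
  expect_equal(rep$average_rank[rep$gene == "Y"], mean(1:10))
  expect_equal(rep$gene[1], "X")

  bad <- mat
  bad$rank3[1] <- NA
  expect_error(aggregate_average_rank(bad), "incomplete")
})

test_that("rank sums are conserved and averages match direct arithmetic", {
  candidates <- sprintf("G%d", 1:6)
  for (seed in c(11, 23, 35)) {
    inp <- assembly_inputs(candidates, seed = seed)
    mat <- assemble_from(inp, candidates)
    n <- length(candidates)
    # conservation holds for every fully scored, fractionally tied criterion
    for (cid in c(1:7)) {
      expect_equal(mean(mat[[paste0("rank", cid)]]), (n + 1) / 2)
    }
    rep <- aggregate_average_rank(mat)
    # exhaustive hand computation of the averages
    for (g in candidates) {
      row <- mat[mat$gene == g, ]
      manual <- sum(vapply(1:10, function(i) row[[paste0("rank", i)]], 0)) / 10
      expect_equal(rep$average_rank[rep$gene == g], manual)
    }
    expect_true(all(rep$average_rank >= 1 & rep$average_rank <= n))
  }
})

test_that("candidate order does not change ranks and dominance orders the report", {
  candidates <- c("D", "A", "C", "B", "E")
  inp <- assembly_inputs(sort(candidates), seed = 42)
  mat1 <- assemble_from(inp, sort(candidates))
  mat2 <- assemble_from(inp, candidates)
  m2 <- dplyr::arrange(tibble::as_tibble(mat2), gene)
  expect_equal(as.data.frame(dplyr::arrange(tibble::as_tibble(mat1), gene)), as.data.frame(m2))

  # dominance: a gene at least as good everywhere and better somewhere precedes
  mat <- tibble::tibble(gene = c("dom", "sub"))
  for (i in 1:10) mat[[paste0("rank", i)]] <- c(1, ifelse(i == 1, 2, 1))
  rep <- aggregate_average_rank(mat)
  expect_equal(rep$gene, c("dom", "sub"))
})
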