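test_that("test/control split intersects disease process lists over the annotated universe", {
  links <- tibble::tibble(
    disease = c(rep("A", 3), rep("B", 3)),
    process_id = c("GO:0000001", "GO:0000002", "GO:0000003",
                   "GO:0000002", "GO:0000003", "GO:0000004")
  )
  ann <- make_annotations(setNames(
    replicate(6, c("G1", "G2"), simplify = FALSE),
    sprintf("GO:%07d", 1:6)
  ))
  sets <- build_test_control_sets(links, "A", "B", ann)
  expect_equal(sets$test, c("GO:0000002", "GO:0000003"))
  expect_equal(sets$control, sprintf("GO:%07d", c(1, 4, 5, 6)))
  expect_equal(length(intersect(sets$test, sets$control)), 0)

  disjoint <- tibble::tibble(
    disease = c("A", "B"), process_id = c("GO:0000001", "GO:0000002")
  )
  expect_error(build_test_control_sets(disjoint, "A", "B", ann), "both diseases")

  # a linked process missing from the annotations is excluded with a warning
  links2 <- dplyr::bind_rows(
    links,
    tibble::tibble(disease = c("A", "B"), process_id = "GO:9999999")
  )
  expect_warning(sets2 <- build_test_control_sets(links2, "A", "B", ann), "excluded")
  expect_false("GO:9999999" %in% c(sets2$test, sets2$control))
})

test_that("Welch statistic matches the hand-derived indicator case", {
  # x = (1,1,0,1), y = (0,1,0,0): means 0.75/0.25, both variances 0.25,
  # t = 0.5 / sqrt(0.25/4 + 0.25/4) = sqrt(2), df = 6 exactly
  w <- welch_t(c(1, 1, 0, 1), c(0, 1, 0, 0))
  expect_equal(w$t, sqrt(2), tolerance = 1e-9)
  expect_equal(w$df, 6)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch statistic agrees with stats::t.test on random samples", {
  set.seed(2024)
  for (i in 1:100) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    w <- welch_t(x, y)
    ref <- stats::t.test(x, y, var.equal = FALSE)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(w$p, ref$p.value, tolerance = 1e-9)
  }
})

make_sets <- function(n_test, n_control) {
  list(
    test = sprintf("GO:%07d", seq_len(n_test)),
    control = sprintf("GO:%07d", n_test + seq_len(n_control))
  )
}

test_that("per-gene specificity scores favour genes concentrated in the test set", {
  sets <- make_sets(4, 8)
  ann <- dplyr::bind_rows(
    make_annotations(setNames(
      replicate(4, "FOCUSED", simplify = FALSE), sets$test
    )),
    # background gene annotated uniformly everywhere
    make_annotations(setNames(
      replicate(12, "UNIFORM", simplify = FALSE), c(sets$test, sets$control)
    )),
    make_annotations(list("GO:0000005" = "SCATTERED"))
  )
  genes <- c("FOCUSED", "SCATTERED", "NOANN", "noann2")
  scores <- criterion7_scores(genes, ann, sets)
  focused <- scores[scores$gene == "FOCUSED", ]
  expect_gt(focused$t_stat, 0)
  expect_equal(focused$p_value, min(scores$p_value))
  expect_equal(focused$mean_test, 1)
  expect_equal(focused$mean_control, 0)

  noann <- scores[scores$gene == "NOANN", ]
  expect_true(noann$degenerate)
  expect_equal(noann$p_value, 1)

  # identical annotation patterns give identical scores (case-insensitive)
  expect_equal(
    scores[scores$gene == "NOANN", -1],
    scores[scores$gene == "noann2", -1]
  )

  # sign coherence across genes
  nd <- scores[!scores$degenerate, ]
  expect_true(all((nd$t_stat > 0) == (nd$mean_test > nd$mean_control)))
})

test_that("criterion-7 ranking puts positive specific genes first, then the rest alphabetically", {
  sets <- make_sets(4, 8)
  ann <- dplyr::bind_rows(
    make_annotations(setNames(replicate(4, "POS1", simplify = FALSE), sets$test)),
    make_annotations(setNames(replicate(3, "POS2", simplify = FALSE), sets$test[1:3])),
    make_annotations(setNames(replicate(6, "NEG", simplify = FALSE), sets$control[1:6]))
  )
  genes <- c("ZZZ_NOANN", "NEG", "POS2", "POS1", "AAA_NOANN")
  scores <- criterion7_scores(genes, ann, sets)
  r <- comorank:::criterion7_rank(scores)
  expect_equal(unname(r[c("POS1", "POS2")]), c(1, 2))
  # negatives/degenerates after the positives, alphabetical
  expect_equal(unname(r[c("AAA_NOANN", "NEG", "ZZZ_NOANN")]), c(3, 4, 5))
})

test_that("specificity tests require usable test and control sets", {
  ann <- make_annotations(list("GO:0000001" = "G1", "GO:0000002" = "G1"))
  expect_error(
    criterion7_scores("G1", ann, list(test = "GO:0000001", control = "GO:0000002")),
    "at least 2"
  )
})
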