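assoc_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      gene = r[1], disease = r[2], source = r[3],
      relevance_score = NA_real_
    )
  }))
}

test_that("disease-network intersection induces the shared-gene subgraph", {
  assoc <- assoc_tbl(
    c("g1", "A", "network_db"), c("g2", "A", "network_db"), c("g3", "A", "network_db"),
    c("g2", "B", "network_db"), c("g3", "B", "network_db"), c("g4", "B", "network_db")
  )
  global <- gene_net(c("g2-g3", "g3-g4"))
  net <- intersect_disease_networks(assoc, "A", "B", global)
  expect_setequal(network_entities(net), c("g2", "g3"))
  expect_equal(nrow(net$edges), 1)

  # disjoint gene sets: empty network plus a warning
  assoc2 <- assoc_tbl(c("g1", "A", "network_db"), c("g2", "B", "network_db"))
  expect_warning(empty <- intersect_disease_networks(assoc2, "A", "B", global), "shared")
  expect_equal(nrow(empty$nodes), 0)

  expect_error(intersect_disease_networks(assoc, "A", "C", global), "'C'")
})

test_that("gene sets are unioned over sources before intersecting", {
  # g2 known to disease A only from the network db and to disease B only
  # from GeneCards: still a shared gene once sources are combined
  assoc <- dplyr::bind_rows(
    assoc_tbl(c("g2", "A", "network_db")),
    tibble::tibble(gene = "G2", disease = "B", source = "genecards", relevance_score = 3)
  )
  global <- gene_net(c("g2-g3"))
  net <- intersect_disease_networks(assoc, "A", "B", global)
  expect_equal(network_entities(net), "g2")
})

test_that("intersection is idempotent", {
  assoc <- assoc_tbl(
    c("g1", "A", "network_db"), c("g2", "A", "network_db"),
    c("g1", "B", "network_db"), c("g2", "B", "network_db")
  )
  global <- gene_net(c("g1-g2", "g2-g3"))
  once <- intersect_disease_networks(assoc, "A", "B", global)
  twice <- intersect_disease_networks(assoc, "A", "B", once)
  expect_equal(dplyr::arrange_all(twice$edges), dplyr::arrange_all(once$edges))
  expect_setequal(network_entities(twice), network_entities(once))
})

test_that("regulatory extraction filters by type and drops isolated nodes", {
  edges <- dplyr::bind_rows(
    gene_edges("A-B", "expression_regulation"),
    gene_edges("C-D", "associative")
  )
  net <- assoc_network(edges)
  reg <- extract_regulatory_subnetwork(net)
  expect_equal(nrow(reg$edges), 1)
  expect_setequal(reg$nodes$id, c("A", "B"))

  only_assoc <- gene_net(c("A-B", "B-C"))
  expect_equal(nrow(extract_regulatory_subnetwork(only_assoc)$edges), 0)

  # subgraph containment on a mixed random network
  mix <- generate_network(30, 0.2, seed = 4)
  sub <- extract_regulatory_subnetwork(mix)
  expect_true(all(
    do.call(paste, sub$edges) %in% do.call(paste, mix$edges)
  ))
  expect_true(all(sub$nodes$id %in% mix$nodes$id))
})

test_that("network summaries count edges by type and nodes by class", {
  edges <- dplyr::bind_rows(
    gene_edges(c("A-B", "B-C"), "associative"),
    gene_edges("A-C", "downregulation")
  )
  s <- summarize_network(assoc_network(edges))
  expect_equal(s$total_edges, 3)
  expect_equal(sum(s$per_type_edge_counts$n), s$total_edges)
  counts <- setNames(s$per_type_edge_counts$n, s$per_type_edge_counts$itype)
  expect_equal(counts[["associative"]], 2)
  expect_equal(counts[["downregulation"]], 1)
  expect_equal(s$n_gene_nodes, 3)

  empty <- extract_regulatory_subnetwork(gene_net("A-B"))
  s0 <- summarize_network(empty)
  expect_equal(s0$total_edges, 0)
  expect_true(all(s0$per_type_edge_counts$n == 0))

  # conservation: total equals the edge multiset size
  net <- generate_network(40, 0.1, seed = 9)
  expect_equal(summarize_network(net)$total_edges, nrow(net$edges))
})

test_that("centralities match closed forms on path, triangle and star", {
  path3 <- compute_centralities(gene_net(c("A-B", "B-C")))
  expect_equal(path3$bc[path3$entity == "B"], 1)
  expect_equal(path3$bc[path3$entity != "B"], c(0, 0))
  expect_equal(path3$cc[path3$entity == "B"], 0)
  expect_equal(path3$dc[path3$entity == "B"], 1)

  tri <- compute_centralities(gene_net(c("A-B", "B-C", "A-C")))
  expect_equal(tri$cc, rep(1, 3))
  expect_equal(tri$bc, rep(0, 3))

  star <- compute_centralities(gene_net(c("H-L1", "H-L2", "H-L3")))
  expect_equal(star$bc[star$entity == "H"], 1)
  expect_equal(star$cc[star$entity == "H"], 0)
  expect_equal(star$dc[star$entity == "H"], 1)

  single <- assoc_network(gene_edges(character(0)),
    nodes = tibble::tibble(id = "A", node_class = "gene")
  )
  expect_error(compute_centralities(single), "fewer than 2")
})

test_that("centralities agree with brute-force enumeration on random graphs", {
  for (seed in 1:8) {
    net <- random_gene_net(sample(5:20, 1), runif(1, 0.1, 0.5), seed = seed * 13)
    cent <- compute_centralities(net)
    adj <- entity_adjacency(net)
    expect_equal(cent$bc, unname(bf_betweenness(adj)), tolerance = 1e-9)
    expect_equal(cent$cc, unname(bf_clustering(adj)), tolerance = 1e-9)
    expect_true(all(cent$dc >= 0 & cent$dc <= 1))
    expect_true(all(cent$bc >= 0 & cent$bc <= 1))
    expect_true(all(cent$cc >= 0 & cent$cc <= 1))
  }
})

test_that("adding an edge never decreases degree centrality", {
  net <- random_gene_net(12, 0.25, seed = 99)
  cent <- compute_centralities(net)
  missing_pair <- NULL
  adj <- entity_adjacency(net)
  for (i in seq_len(nrow(adj))) {
    for (j in seq_len(ncol(adj))) {
      if (i < j && adj[i, j] == 0L) {
        missing_pair <- c(rownames(adj)[i], colnames(adj)[j])
        break
      }
    }
    if (!is.null(missing_pair)) break
  }
  skip_if(is.null(missing_pair), "graph is complete")
  bigger <- assoc_network(
    dplyr::bind_rows(net$edges, gene_edges(paste(missing_pair, collapse = "-"))),
    nodes = net$nodes
  )
  cent2 <- compute_centralities(bigger)
  merged <- dplyr::left_join(cent, cent2, by = "entity", suffix = c("", "_after"))
  expect_true(all(merged$degree_raw_after >= merged$degree_raw))
  expect_true(all(merged$dc_after >= merged$dc))
})

test_that("cross-talk specificity is the subnetwork/global link ratio", {
  expect_equal(cross_talk_specificity(5, 50), 0.1)
  expect_equal(cross_talk_specificity(7, 7), 1)
  expect_error(cross_talk_specificity(1, 0), "undefined")
  expect_error(cross_talk_specificity(8, 7), "more links")

  global <- gene_net(c("A-B", "A-C", "A-D", "B-C"))
  sub <- gene_net(c("A-B", "A-C", "B-C"))
  cts <- network_cts(sub, global)
  expect_equal(cts$cts[cts$entity == "A"], 2 / 3)
  expect_equal(cts$cts[cts$entity == "B"], 1)
})

test_that("hub detection applies inclusive bc/cc cutoffs and a strict degree cutoff", {
  recs <- tibble::tibble(
    entity = c("hub", "deg40", "lowbc"),
    degree_raw = c(41L, 40L, 100L),
    dc = 0.5,
    bc = c(0.006, 0.006, 0.004),
    cc = c(0.25, 0.25, 0.9)
  )
  expect_equal(detect_hubs(recs), "hub")
  # boundary: bc and cc exactly at the cutoff still qualify
  boundary <- tibble::tibble(
    entity = "edge", degree_raw = 41L, dc = 0.1, bc = 0.005, cc = 0.2
  )
  expect_equal(detect_hubs(boundary), "edge")
})
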