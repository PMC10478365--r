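#' Configuration for a synthetic comorbidity study
#'
#' Bundles every knob of the synthetic study generator. Defaults emulate
#' a desk-scale two-disease study: a few hundred genes, a quarter of
#' them shared between the diseases, a handful of planted "driver"
#' genes carrying the statistical signatures of comorbidity candidates,
#' and a typed network whose edge-type proportions follow the breakdown
#' typical of literature-mined disease networks (generic associations
#' dominate).
#'
#' @param n_genes Total number of genes.
#' @param n_processes Number of GO biological processes.
#' @param overlap_fraction Fraction of genes associated with both
#'   diseases, in (0, 1).
#' @param n_drivers Number of planted driver genes (must not exceed the
#'   overlap size).
#' @param edge_density Probability that an unordered gene pair is
#'   connected in the global network, in (0, 1].
#' @param driver_signal Probability boost drivers receive in
#'   annotations, SNPs and external scores, in \[0, 1\]; 0 makes
#'   drivers indistinguishable from background.
#' @param seed Integer seed; the full bundle is deterministic given the
#'   config.
#' @param disease_a,disease_b Disease names used throughout the bundle.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200, n_processes = 120,
                             overlap_fraction = 0.25, n_drivers = 5,
                             edge_density = 0.05, driver_signal = 0.9,
                             seed = 1L,
                             disease_a = "diseaseA", disease_b = "diseaseB") {
  assert_scalar_number(n_genes, "n_genes", lower = 10)
  assert_scalar_number(n_processes, "n_processes", lower = 10)
  assert_scalar_number(overlap_fraction, "overlap_fraction")
  if (overlap_fraction <= 0 || overlap_fraction >= 1) {
    abort("overlap_fraction must lie strictly within (0, 1).")
  }
  assert_scalar_number(edge_density, "edge_density")
  if (edge_density <= 0 || edge_density > 1) {
    abort("edge_density must lie in (0, 1].")
  }
  assert_scalar_number(driver_signal, "driver_signal", lower = 0, upper = 1)
  overlap_size <- round(overlap_fraction * n_genes)
  if (n_drivers > overlap_size) {
    abort(sprintf(
      "n_drivers (%d) exceeds the disease overlap size (%d).",
      n_drivers, overlap_size
    ))
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_processes = as.integer(n_processes),
      overlap_fraction = overlap_fraction, n_drivers = as.integer(n_drivers),
      edge_density = edge_density, driver_signal = driver_signal,
      seed = as.integer(seed), disease_a = disease_a, disease_b = disease_b
    ),
    class = "synthetic_config"
  )
}

# one pseudo-random stream per generated artifact: adding an artifact
# never perturbs the others
artifact_seed <- function(seed, artifact) {
  offsets <- c(
    split = 11L, network = 23L, assoc = 37L, go = 53L,
    snp = 71L, scores = 89L
  )
  (as.integer(seed) * 101L + offsets[[artifact]]) %% 2147483587L
}

default_type_mix <- function() {
  counts <- c(
    activity_regulation = 623, degradation_regulation = 16,
    expression_regulation = 863, transport_regulation = 4931,
    downregulation = 4838, associative = 131844, protein_protein = 5863
  )
  counts / sum(counts)
}

#' Generate a random typed association network
#'
#' Samples a simple graph over the given genes at the requested edge
#' density and assigns each edge an interaction type drawn from
#' `type_mix`. Regulatory edges run protein to gene, protein-protein
#' edges connect protein nodes, and associative edges connect gene
#' nodes, so symbols appear as both gene and protein nodes as in
#' literature-mined networks.
#'
#' @param genes Gene symbols (or a single count, expanded to symbols).
#' @param edge_density Probability of each unordered pair, in (0, 1].
#' @param type_mix Named proportions over [interaction_types()]; must
#'   sum to 1 (within 1e-9). Defaults to the breakdown of a typical
#'   literature-mined disease network.
#' @param seed Integer seed.
#' @return An [assoc_network()].
#' @export
generate_network <- function(genes, edge_density, type_mix = default_type_mix(),
                             seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("G%04d", seq_len(genes))
  }
  if (edge_density <= 0 || edge_density > 1) {
    abort("edge_density must lie in (0, 1].")
  }
  if (!setequal(names(type_mix), interaction_types())) {
    abort("type_mix must name all seven interaction types.")
  }
  if (abs(sum(type_mix) - 1) > 1e-9) {
    abort("type_mix proportions must sum to 1.")
  }
  n <- length(genes)
  set.seed(artifact_seed(seed, "network"))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_density
  pairs <- pairs[keep, , drop = FALSE]
  itype <- sample(
    interaction_types(), nrow(pairs),
    replace = TRUE, prob = type_mix[interaction_types()]
  )
  class_for <- function(itype, end) {
    dplyr::case_when(
      itype == "protein_protein" ~ "protein",
      itype == "associative" ~ "gene",
      end == "source" ~ "protein",
      TRUE ~ "gene"
    )
  }
  edges <- tibble(
    source = genes[pairs[, 1]],
    source_class = class_for(itype, "source"),
    target = genes[pairs[, 2]],
    target_class = class_for(itype, "target"),
    itype = itype
  )
  assoc_network(
    edges,
    nodes = tibble(id = genes, node_class = "gene"),
    name = "synthetic global network"
  )
}

#' Build a typed network with exact per-type edge counts
#'
#' Deterministically constructs a network with the requested numbers of
#' gene and protein nodes and exactly the requested number of edges of
#' each interaction type (protein nodes reuse the first gene symbols,
#' as symbols do across node classes in curated networks). Useful for
#' reproducing published network accounting.
#'
#' @param n_gene_nodes,n_protein_nodes Node counts by class.
#' @param type_counts Named integer vector over (a subset of)
#'   [interaction_types()].
#' @param name Network name.
#' @return An [assoc_network()] whose summary reproduces the counts.
#' @export
network_from_type_counts <- function(n_gene_nodes, n_protein_nodes,
                                     type_counts, name = "constructed network") {
  check_itype(names(type_counts))
  ng <- as.integer(n_gene_nodes)
  np <- as.integer(n_protein_nodes)
  if (np > ng) abort("Protein nodes reuse gene symbols; need n_protein_nodes <= n_gene_nodes.")
  nodes <- bind_rows(
    tibble(id = sprintf("N%04d", seq_len(ng)), node_class = "gene"),
    tibble(id = sprintf("N%04d", seq_len(np)), node_class = "protein")
  )
  n <- nrow(nodes)
  capacity <- n * (n - 1)
  edges <- purrr::imap(type_counts, function(cnt, ty) {
    cnt <- as.integer(cnt)
    if (cnt > capacity) {
      abort(sprintf(
        "Cannot place %d '%s' edges on %d nodes (max %d ordered pairs).",
        cnt, ty, n, capacity
      ))
    }
    if (cnt == 0L) return(NULL)
    idx <- seq_len(cnt) - 1L
    s <- idx %/% (n - 1L) + 1L
    off <- idx %% (n - 1L)
    t <- (s - 1L + 1L + off) %% n + 1L
    tibble(
      source = nodes$id[s], source_class = nodes$node_class[s],
      target = nodes$id[t], target_class = nodes$node_class[t],
      itype = ty
    )
  })
  assoc_network(bind_rows(edges), nodes = nodes, name = name)
}

#' Generate a complete synthetic comorbidity study
#'
#' Produces every input the prioritization pipeline consumes, with
#' planted driver genes: two overlapping disease gene sets, a typed
#' global network, GO annotations in which drivers are preferentially
#' annotated to the disease-shared processes, an SNP catalog in which
#' drivers preferentially carry brain-eQTL SNPs with common minor
#' alleles and disease associations, and three external score tables
#' favouring drivers in expectation. With `driver_signal = 0` drivers
#' are statistically indistinguishable from the other shared genes.
#'
#' @param config A [synthetic_config()].
#' @return A list with `bundle` (fields `assoc`, `network`,
#'   `annotations`, `links`, `snp_catalog`, `external`,
#'   `comorbid_diseases`, `disease_a`, `disease_b`) and `truth`
#'   (`drivers`, `shared_processes`, `driver_snp` flags).
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be created with synthetic_config().")
  }
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  m <- round(cfg$overlap_fraction * cfg$n_genes)

  set.seed(artifact_seed(cfg$seed, "split"))
  shuffled <- sample(genes)
  shared <- sort(shuffled[seq_len(m)])
  rest <- shuffled[-seq_len(m)]
  half <- length(rest) %/% 2
  only_a <- rest[seq_len(half)]
  only_b <- rest[-seq_len(half)]
  drivers <- sort(sample(shared, cfg$n_drivers))

  network <- generate_network(genes, cfg$edge_density, seed = cfg$seed)

  set.seed(artifact_seed(cfg$seed, "assoc"))
  assoc_rows <- function(gs, disease) {
    src <- sample(c("network_db", "genecards", "both"), length(gs),
      replace = TRUE, prob = c(0.45, 0.3, 0.25)
    )
    bind_rows(
      tibble(
        gene = gs[src != "genecards"], disease = disease,
        source = "network_db", relevance_score = NA_real_
      ),
      tibble(
        gene = gs[src != "network_db"], disease = disease,
        source = "genecards",
        relevance_score = round(runif(sum(src != "network_db"), 1, 100), 2)
      )
    )
  }
  assoc <- bind_rows(
    assoc_rows(c(shared, only_a), cfg$disease_a),
    assoc_rows(c(shared, only_b), cfg$disease_b)
  )

  # GO annotations with planted enrichment of drivers in shared processes
  set.seed(artifact_seed(cfg$seed, "go"))
  processes <- sprintf("GO:%07d", seq_len(cfg$n_processes))
  n_shared_proc <- max(4L, round(0.1 * cfg$n_processes))
  shared_proc <- processes[seq_len(n_shared_proc)]
  p_bg <- 0.06
  memb <- matrix(
    runif(cfg$n_genes * cfg$n_processes) < p_bg,
    nrow = cfg$n_genes, dimnames = list(genes, processes)
  )
  # shared genes are mildly over-annotated to the disease-shared
  # processes (so those processes enrich in the comorbidity query);
  # drivers much more strongly -- both effects vanish at zero signal
  p_shared <- p_bg + 0.3 * cfg$driver_signal
  memb[shared, shared_proc] <-
    runif(length(shared) * n_shared_proc) < p_shared
  p_driver <- p_bg + cfg$driver_signal * (1 - p_bg)
  memb[drivers, shared_proc] <-
    runif(length(drivers) * n_shared_proc) < p_driver
  for (p in which(colSums(memb) == 0L)) memb[sample(cfg$n_genes, 1L), p] <- TRUE
  idx <- which(memb, arr.ind = TRUE)
  annotations <- tibble(
    process_id = processes[idx[, 2]],
    process_name = paste("process", processes[idx[, 2]]),
    gene = genes[idx[, 1]]
  ) |>
    arrange(.data$process_id, .data$gene)
  extra_a <- sample(setdiff(processes, shared_proc), min(8L, cfg$n_processes - n_shared_proc))
  extra_b <- sample(setdiff(processes, c(shared_proc, extra_a)),
    min(8L, cfg$n_processes - n_shared_proc - length(extra_a)))
  links <- bind_rows(
    tibble(disease = cfg$disease_a, process_id = c(shared_proc, extra_a)),
    tibble(disease = cfg$disease_b, process_id = c(shared_proc, extra_b))
  )

  # SNP catalog with planted qualifying/disease-associated SNPs in drivers
  set.seed(artifact_seed(cfg$seed, "snp"))
  comorbid_diseases <- c("comorbid syndrome 1", "comorbid syndrome 2", "comorbid syndrome 3")
  gene_length <- setNames(sample(20000:200000, cfg$n_genes, replace = TRUE), genes)
  base_rows <- purrr::map(genes, function(g) {
    k <- rpois(1, 2)
    if (k == 0L) return(NULL)
    tibble(
      snp_id = sprintf("rs%s_%d", sub("^G", "", g), seq_len(k)),
      gene = g,
      eqtl_tissues = purrr::map(seq_len(k), function(i) {
        if (runif(1) < 0.4) c("brain") else sample(c("liver", "blood", "muscle"), 1)
      }),
      maf = round(runif(k, 0.01, 0.5), 4),
      associated_diseases = purrr::map(seq_len(k), function(i) {
        r <- runif(1)
        if (r < 0.04) sample(c(cfg$disease_a, cfg$disease_b), 1)
        else if (r < 0.08) sample(comorbid_diseases, 1)
        else character(0)
      }),
      gene_length_nt = unname(gene_length[g])
    )
  })
  driver_snp <- setNames(rep(FALSE, length(drivers)), drivers)
  planted_rows <- purrr::map(drivers, function(g) {
    if (runif(1) >= cfg$driver_signal) return(NULL)
    driver_snp[[g]] <<- TRUE
    tibble(
      snp_id = sprintf("rs%s_p%d", sub("^G", "", g), 1:2),
      gene = g,
      eqtl_tissues = list("brain", "brain"),
      maf = round(runif(2, 0.05, 0.5), 4),
      associated_diseases = list(
        sample(c(cfg$disease_a, cfg$disease_b), 1),
        sample(comorbid_diseases, 1)
      ),
      gene_length_nt = unname(gene_length[g])
    )
  })
  snp_catalog <- bind_rows(base_rows, planted_rows)

  # external prioritizer scores: drivers better in expectation
  set.seed(artifact_seed(cfg$seed, "scores"))
  boost <- as.numeric(genes %in% drivers) * cfg$driver_signal
  external <- list(
    external_scores(
      tibble(gene = genes, score = round(runif(cfg$n_genes, 0, 50) + boost * 100, 3)), 1L
    ),
    external_scores(
      tibble(gene = genes, score = signif(runif(cfg$n_genes)^(1 + 9 * boost), 6)), 2L
    ),
    external_scores(
      tibble(gene = genes, score = round(runif(cfg$n_genes) + boost * 2, 6)), 3L
    )
  )

  list(
    bundle = list(
      assoc = assoc, network = network,
      annotations = annotations, links = links,
      snp_catalog = snp_catalog, external = external,
      comorbid_diseases = comorbid_diseases,
      disease_a = cfg$disease_a, disease_b = cfg$disease_b
    ),
    truth = list(
      drivers = drivers, shared_processes = shared_proc,
      driver_snp = driver_snp
    )
  )
}

#' Write a synthetic study bundle to a directory
#'
#' Materializes every bundle component in the flat-file formats the
#' readers consume, plus a `truth.json` with the planted drivers.
#'
#' @param study A study from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- study$bundle
  write_network(b$network, file.path(dir, "network.tsv"))
  readr::write_tsv(b$assoc, file.path(dir, "disease_genes.tsv"))
  ann <- b$annotations |>
    group_by(.data$process_id, .data$process_name) |>
    summarise(genes = paste(.data$gene, collapse = "\t"), .groups = "drop")
  readr::write_lines(
    sprintf("%s\t%s\t%s", ann$process_id, ann$process_name, ann$genes),
    file.path(dir, "go_annotations.gmt")
  )
  readr::write_tsv(b$links, file.path(dir, "disease_processes.tsv"))
  snp_flat <- b$snp_catalog |>
    mutate(
      eqtl_tissues = purrr::map_chr(.data$eqtl_tissues, paste, collapse = ";"),
      associated_diseases = purrr::map_chr(.data$associated_diseases, paste, collapse = ";")
    )
  readr::write_tsv(snp_flat, file.path(dir, "snp_catalog.tsv"))
  for (i in 1:3) {
    readr::write_tsv(
      as_tibble(b$external[[i]]),
      file.path(dir, sprintf("external_scores_criterion%d.tsv", i))
    )
  }
  readr::write_lines(b$comorbid_diseases, file.path(dir, "comorbid_diseases.txt"))
  jsonlite::write_json(
    study$truth,
    file.path(dir, "truth.json"),
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(dir)
}

#' Fraction of planted drivers recovered in the top of a report
#'
#' @param priority A `priority_report`.
#' @param truth Planted truth from [generate_study()].
#' @param k Number of top rows to inspect.
#' @return Fraction of drivers among the first `k` rows, in \[0, 1\].
#' @export
recovery_report <- function(priority, truth, k) {
  if (length(truth$drivers) == 0L) abort("Planted truth has no drivers.")
  if (k > nrow(priority)) abort("k exceeds the report size.")
  top <- sym_key(head(priority$gene, k))
  mean(sym_key(truth$drivers) %in% top)
}
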