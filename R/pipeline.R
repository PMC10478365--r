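empty_centralities <- function() {
  out <- tibble(
    entity = character(0), degree_raw = integer(0),
    dc = numeric(0), bc = numeric(0), cc = numeric(0)
  )
  class(out) <- c("centrality_tbl", class(out))
  out
}

empty_enrichment <- function() {
  out <- tibble(
    process_id = character(0), process_name = character(0),
    k = integer(0), K = integer(0), n = integer(0), N = integer(0),
    p_value = numeric(0), q_value = numeric(0), enriched = logical(0),
    members = list()
  )
  class(out) <- c("enrichment_tbl", class(out))
  out
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      parent = e
    )
  })
}

#' Run the prioritization pipeline on an in-memory study bundle
#'
#' Executes every stage -- disease-network intersection, regulatory
#' extraction, enrichment of both networks, criterion-4 counts,
#' centralities (criteria 5-6), test/control process split and
#' criterion-7 specificity, SNP criteria 8-10, rank-matrix assembly and
#' average-rank aggregation -- and returns the priority report together
#' with all intermediates.
#'
#' @param bundle A list with fields `assoc`, `network`, `annotations`,
#'   `links`, `snp_catalog`, `external` (list of up to three
#'   `external_scores` tables, may be `NULL`), `comorbid_diseases`,
#'   `disease_a`, `disease_b` -- the shape [generate_study()] produces
#'   and [run_pipeline()] assembles from files.
#' @param enrichment_alpha FDR threshold for calling a process enriched
#'   (default 0.01).
#' @param specificity_alpha FDR threshold for the criterion-7
#'   `specific` flag (default 0.05).
#' @param snp_tissue Required eQTL tissue (default `"brain"`).
#' @param snp_maf_min Minor-allele-frequency floor (default 0.05).
#' @param regulatory Edge types of the regulatory subnetwork.
#' @return A list of class `comorank_run`: `report` (the
#'   `priority_report`), `rank_matrix`, `candidates`, and the
#'   intermediates (`complete_network`, `regulatory_network`,
#'   `enrichment_complete`, `enrichment_regulatory`, `criterion4`,
#'   `centralities_complete`, `centralities_regulatory`, `specificity`,
#'   `snp_ranks`, `qualifying_snps`).
#' @export
prioritize_study <- function(bundle,
                             enrichment_alpha = 0.01,
                             specificity_alpha = 0.05,
                             snp_tissue = "brain",
                             snp_maf_min = 0.05,
                             regulatory = regulatory_types()) {
  a <- bundle$disease_a
  b <- bundle$disease_b

  complete <- run_stage("intersect", intersect_disease_networks(
    bundle$assoc, a, b, bundle$network
  ))
  candidates <- network_entities(complete)
  if (length(candidates) == 0L) {
    abort("No genes are shared between the two diseases in the network; nothing to prioritize.")
  }

  regulatory_net <- run_stage(
    "regulatory",
    extract_regulatory_subnetwork(complete, regulatory)
  )

  enr_complete <- run_stage("enrichment_complete", enrich_processes(
    candidates, bundle$annotations,
    alpha = enrichment_alpha
  ))
  reg_entities <- network_entities(regulatory_net)
  enr_reg <- if (length(reg_entities) == 0L) {
    empty_enrichment()
  } else {
    run_stage("enrichment_regulatory", enrich_processes(
      reg_entities, bundle$annotations,
      alpha = enrichment_alpha
    ))
  }
  c4 <- run_stage("criterion4", criterion4_counts(enr_complete, enr_reg, candidates))

  cent_complete <- run_stage("centralities_complete", compute_centralities(complete))
  cent_reg <- if (length(reg_entities) < 2L) {
    empty_centralities()
  } else {
    run_stage("centralities_regulatory", compute_centralities(regulatory_net))
  }

  sets <- run_stage("test_control_sets", build_test_control_sets(
    bundle$links, a, b, bundle$annotations
  ))
  c7 <- run_stage("criterion7", criterion7_scores(
    candidates, bundle$annotations, sets,
    alpha = specificity_alpha
  ))

  qualifying <- run_stage("snp_filter", filter_qualifying_snps(
    bundle$snp_catalog,
    tissue = snp_tissue, maf_min = snp_maf_min
  ))
  c8 <- run_stage("criterion8", binary_snp_criterion(candidates, qualifying, 8L))
  c9 <- run_stage("criterion9", binary_snp_criterion(
    candidates, qualifying, 9L,
    disease_whitelist = c(a, b)
  ))
  c10 <- run_stage("criterion10", binary_snp_criterion(
    candidates, qualifying, 10L,
    disease_whitelist = bundle$comorbid_diseases
  ))

  mat <- run_stage("assemble", assemble_rank_matrix(
    bundle$external %||% list(), c4, cent_complete, cent_reg,
    c7, c8, c9, c10, candidates
  ))
  report <- run_stage("aggregate", aggregate_average_rank(mat))

  structure(
    list(
      report = report, rank_matrix = mat, candidates = candidates,
      complete_network = complete, regulatory_network = regulatory_net,
      enrichment_complete = enr_complete, enrichment_regulatory = enr_reg,
      criterion4 = c4,
      centralities_complete = cent_complete,
      centralities_regulatory = cent_reg,
      specificity = c7,
      snp_ranks = list(c8 = c8, c9 = c9, c10 = c10),
      qualifying_snps = qualifying,
      params = list(
        enrichment_alpha = enrichment_alpha,
        specificity_alpha = specificity_alpha,
        snp_tissue = snp_tissue, snp_maf_min = snp_maf_min,
        regulatory = regulatory,
        disease_a = a, disease_b = b
      )
    ),
    class = "comorank_run"
  )
}

#' @export
print.comorank_run <- function(x, ...) {
  cat(sprintf(
    "<comorank_run> %d candidate genes (%s vs %s)\nTop genes: %s\n",
    length(x$candidates), x$params$disease_a, x$params$disease_b,
    paste(head(x$report$gene, 5), collapse = ", ")
  ))
  invisible(x)
}

#' Run the full pipeline from a file-based configuration
#'
#' Reads every input named in the config, runs [prioritize_study()],
#' and materializes every intermediate plus the final priority report
#' and a JSON run manifest (thresholds and input file digests) in the
#' output directory.
#'
#' @param config A list, or the path to a YAML file, with entries:
#'   `network` (path; optionally `network_dialect`), `disease_genes`,
#'   `go_annotations`, `disease_processes`, `snp_catalog`,
#'   `comorbid_diseases` (paths), `external_scores` (named or ordered
#'   list of up to three paths, optional), `disease_a`, `disease_b`,
#'   `output_dir`, and optional thresholds `enrichment_alpha`,
#'   `specificity_alpha`, `snp_tissue`, `snp_maf_min`,
#'   `regulatory_types`.
#' @return The `comorank_run` result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  req <- c(
    "network", "disease_genes", "go_annotations", "disease_processes",
    "snp_catalog", "comorbid_diseases", "disease_a", "disease_b", "output_dir"
  )
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys) > 0L) {
    abort(sprintf("Config lacks key(s): %s.", paste(missing_keys, collapse = ", ")))
  }

  network <- run_stage("read_network", read_network(
    config$network,
    dialect = config$network_dialect %||% "tsv"
  ))
  assoc <- run_stage("read_disease_genes", read_disease_genes(config$disease_genes))
  go <- run_stage("read_go_inputs", read_go_inputs(
    config$go_annotations, config$disease_processes
  ))
  snp_catalog <- run_stage("read_snp_catalog", read_snp_catalog(config$snp_catalog))
  comorbid <- run_stage(
    "read_comorbid_diseases",
    read_comorbid_diseases(config$comorbid_diseases)
  )
  ext_paths <- config$external_scores %||% list()
  external <- purrr::imap(ext_paths, function(p, i) {
    cid <- if (is.character(i) && nzchar(i)) {
      as.integer(sub("^criterion", "", i))
    } else {
      as.integer(i)
    }
    run_stage(
      sprintf("read_external_scores_%d", cid),
      read_external_scores(p, cid)
    )
  })

  bundle <- list(
    assoc = assoc, network = network,
    annotations = go$annotations, links = go$links,
    snp_catalog = snp_catalog, external = unname(external),
    comorbid_diseases = comorbid,
    disease_a = config$disease_a, disease_b = config$disease_b
  )
  run <- prioritize_study(
    bundle,
    enrichment_alpha = config$enrichment_alpha %||% 0.01,
    specificity_alpha = config$specificity_alpha %||% 0.05,
    snp_tissue = config$snp_tissue %||% "brain",
    snp_maf_min = config$snp_maf_min %||% 0.05,
    regulatory = config$regulatory_types %||% regulatory_types()
  )

  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_priority_report(run$report, file.path(out_dir, "priority_report.tsv"))
  readr::write_tsv(as_tibble(run$rank_matrix), file.path(out_dir, "rank_matrix.tsv"))
  write_network(run$complete_network, file.path(out_dir, "complete_network.tsv"))
  write_network(run$regulatory_network, file.path(out_dir, "regulatory_network.tsv"))
  write_network_summary(
    summarize_network(run$complete_network),
    file.path(out_dir, "complete_network_summary.tsv")
  )
  write_enrichment(run$enrichment_complete, file.path(out_dir, "enrichment_complete.tsv"))
  write_enrichment(run$enrichment_regulatory, file.path(out_dir, "enrichment_regulatory.tsv"))
  readr::write_tsv(run$criterion4, file.path(out_dir, "criterion4_counts.tsv"))
  readr::write_tsv(
    as_tibble(run$centralities_complete),
    file.path(out_dir, "centralities_complete.tsv")
  )
  readr::write_tsv(
    as_tibble(run$centralities_regulatory),
    file.path(out_dir, "centralities_regulatory.tsv")
  )
  readr::write_tsv(as_tibble(run$specificity), file.path(out_dir, "criterion7_specificity.tsv"))
  for (nm in names(run$snp_ranks)) {
    flat <- run$snp_ranks[[nm]] |>
      mutate(evidence_snp_ids = purrr::map_chr(.data$evidence_snp_ids, paste, collapse = ";"))
    readr::write_tsv(flat, file.path(out_dir, sprintf("criterion%s_ranks.tsv", sub("^c", "", nm))))
  }

  input_files <- c(
    network = config$network, disease_genes = config$disease_genes,
    go_annotations = config$go_annotations,
    disease_processes = config$disease_processes,
    snp_catalog = config$snp_catalog,
    comorbid_diseases = config$comorbid_diseases,
    unlist(ext_paths)
  )
  manifest <- list(
    params = run$params,
    seed = config$seed %||% NA,
    external_criteria = attr(run$rank_matrix, "provenance"),
    input_digests = as.list(tools::md5sum(input_files))
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", force = TRUE
  )
  invisible(run)
}
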