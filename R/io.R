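#' Read a typed association network
#'
#' Reads an edge list in one of two dialects. The `tsv` dialect expects
#' a header `source, source_class, target, target_class,
#' interaction_type`; the `sif` dialect uses the interaction type as the
#' relation token (`source<TAB>type<TAB>target1<TAB>target2...`) and
#' assigns every node the class `protein`. Lines starting with `#` are
#' ignored. Duplicate identical edges are collapsed.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @param nodes_path Optional two-column TSV (`id`, `node_class`) adding
#'   nodes (e.g. isolated ones) beyond those induced by the edges.
#' @param name Network name; defaults to the file name.
#' @return An [assoc_network()].
#' @export
read_network <- function(path, dialect = c("tsv", "sif"),
                         nodes_path = NULL, name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  name <- name %||% basename(path)

  if (dialect == "tsv") {
    raw <- readr::read_tsv(
      path,
      comment = "#", show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    needed <- c("source", "source_class", "target", "target_class", "interaction_type")
    if (!all(needed %in% names(raw))) {
      abort(sprintf(
        "Network TSV must have header: %s.", paste(needed, collapse = ", ")
      ))
    }
    check_itype(raw$interaction_type, line_no = seq_len(nrow(raw)) + 1L)
    edges <- tibble(
      source = raw$source, source_class = raw$source_class,
      target = raw$target, target_class = raw$target_class,
      itype = raw$interaction_type
    )
  } else {
    lines <- readr::read_lines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    rows <- purrr::map2(which(keep), lines[keep], function(ln, l) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3L) {
        abort(sprintf("SIF line %d has fewer than 3 fields.", ln))
      }
      check_itype(parts[2], line_no = ln)
      tibble(
        source = parts[1], source_class = "protein",
        target = parts[-(1:2)], target_class = "protein",
        itype = parts[2]
      )
    })
    edges <- bind_rows(rows)
  }

  nodes <- NULL
  if (!is.null(nodes_path)) {
    nodes <- readr::read_tsv(
      nodes_path,
      comment = "#", show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  net <- assoc_network(edges, nodes = nodes, name = name)
  message(sprintf(
    "Read network '%s': %d nodes, %d edges.", name, nrow(net$nodes), nrow(net$edges)
  ))
  net
}

#' Write a typed association network as TSV
#'
#' @param net An [assoc_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  out <- net$edges
  names(out)[names(out) == "itype"] <- "interaction_type"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a disease-gene association table
#'
#' Expects a TSV with header `gene, disease, source, relevance_score`.
#' `source` is `network_db` (curated association network) or
#' `genecards`; a relevance score may only accompany `genecards` rows
#' and must be nonnegative. Duplicate `(gene, disease, source)` rows are
#' deduplicated with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene`, `disease`, `source`,
#'   `relevance_score` (`NA` when absent).
#' @export
read_disease_genes <- function(path) {
  raw <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(),
      disease = readr::col_character(),
      source = readr::col_character(),
      relevance_score = readr::col_double()
    )
  )
  needed <- c("gene", "disease", "source", "relevance_score")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("Disease-gene TSV must have header: %s.", paste(needed, collapse = ", ")))
  }
  bad_src <- setdiff(unique(raw$source), c("network_db", "genecards"))
  if (length(bad_src) > 0L) {
    abort(sprintf("Unknown source value(s): %s.", paste(bad_src, collapse = ", ")))
  }
  if (any(raw$source == "network_db" & !is.na(raw$relevance_score))) {
    abort("relevance_score is only valid on genecards rows.")
  }
  if (any(!is.na(raw$relevance_score) & raw$relevance_score < 0)) {
    abort("relevance_score must be nonnegative.")
  }
  out <- distinct(raw, .data$gene, .data$disease, .data$source, .keep_all = TRUE)
  if (nrow(out) < nrow(raw)) {
    warn(sprintf(
      "Dropped %d duplicate (gene, disease, source) row(s).", nrow(raw) - nrow(out)
    ))
  }
  out
}

#' Read GO biological-process inputs
#'
#' Reads a gene annotation file (either two-column `process_id, gene`
#' TSV or GMT-style `process_id<TAB>name<TAB>gene1<TAB>gene2...`) and a
#' two-column disease-process link file (`disease, process_id`).
#'
#' @param annotation_path Path to the annotation file.
#' @param links_path Path to the disease-process link file.
#' @return A list with `annotations` (tibble `process_id`,
#'   `process_name`, `gene`) and `links` (tibble `disease`,
#'   `process_id`).
#' @export
read_go_inputs <- function(annotation_path, links_path) {
  lines <- readr::read_lines(annotation_path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2L)) {
    abort("Annotation lines must have at least 2 tab-separated fields.")
  }
  # heuristics: a GMT line's 2nd field is a free-text name, a 2-column
  # line's 2nd field is a gene; with exactly 2 columns treat as (id, gene)
  gmt <- any(n_fields > 2L)
  annotations <- bind_rows(purrr::map(fields, function(p) {
    if (gmt) {
      tibble(process_id = p[1], process_name = p[2], gene = p[-(1:2)])
    } else {
      tibble(process_id = p[1], process_name = NA_character_, gene = p[2])
    }
  }))
  check_go_ids(annotations$process_id)
  annotations <- distinct(annotations)
  if (nrow(annotations) == 0L) abort("Annotation file is empty.")

  links <- readr::read_tsv(
    links_path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("disease", "process_id") %in% names(links))) {
    abort("Links file must have header: disease, process_id.")
  }
  check_go_ids(links$process_id)
  links <- distinct(links[, c("disease", "process_id")])

  message(sprintf(
    "GO inputs: %d processes, universe of %d genes, %d disease-process links.",
    dplyr::n_distinct(annotations$process_id),
    dplyr::n_distinct(annotations$gene), nrow(links)
  ))
  list(annotations = annotations, links = links)
}

#' Read an SNP catalog
#'
#' Expects a TSV with header `snp_id, gene, eqtl_tissues, maf,
#' associated_diseases, gene_length_nt`. Multi-valued fields are
#' semicolon-joined; `associated_diseases` may be blank.
#'
#' @param path Path to the TSV file.
#' @return A tibble with list-columns `eqtl_tissues` and
#'   `associated_diseases`.
#' @export
read_snp_catalog <- function(path) {
  raw <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      snp_id = readr::col_character(),
      gene = readr::col_character(),
      eqtl_tissues = readr::col_character(),
      maf = readr::col_double(),
      associated_diseases = readr::col_character(),
      gene_length_nt = readr::col_double()
    )
  )
  needed <- c("snp_id", "gene", "eqtl_tissues", "maf", "associated_diseases", "gene_length_nt")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("SNP catalog must have header: %s.", paste(needed, collapse = ", ")))
  }
  if (any(is.na(raw$maf) | raw$maf < 0 | raw$maf > 1)) {
    abort("maf must lie in [0, 1].")
  }
  if (any(is.na(raw$gene_length_nt) | raw$gene_length_nt <= 0)) {
    abort("gene_length_nt must be a positive integer.")
  }
  split_multi <- function(x) {
    purrr::map(x, function(v) {
      if (is.na(v) || !nzchar(trimws(v))) character(0) else trimws(strsplit(v, ";", fixed = TRUE)[[1]])
    })
  }
  out <- tibble(
    snp_id = raw$snp_id,
    gene = raw$gene,
    eqtl_tissues = split_multi(raw$eqtl_tissues),
    maf = raw$maf,
    associated_diseases = split_multi(raw$associated_diseases),
    gene_length_nt = as.integer(raw$gene_length_nt)
  )
  distinct(out, .data$snp_id, .data$gene, .keep_all = TRUE)
}

#' Read an external prioritizer score table
#'
#' Criteria 1-3 consume score tables produced by external gene
#' prioritizers. The comparison direction is fixed by the criterion:
#' criterion 1 is a relevance score (higher is better), criterion 2 a
#' p-value (lower is better), criterion 3 an average score (higher is
#' better).
#'
#' @param path Path to a two-column TSV (`gene`, `score`).
#' @param criterion_id Integer, 1, 2 or 3.
#' @return A tibble (`gene`, `score`) with attributes `criterion_id` and
#'   `direction` and class `external_scores`.
#' @export
read_external_scores <- function(path, criterion_id) {
  if (!criterion_id %in% 1:3) {
    abort("criterion_id must be 1, 2 or 3 for external score tables.")
  }
  raw <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(),
      score = readr::col_double()
    )
  )
  if (!all(c("gene", "score") %in% names(raw))) {
    abort("External score table must have header: gene, score.")
  }
  if (anyDuplicated(sym_key(raw$gene))) {
    abort("External score table has duplicate genes.")
  }
  external_scores(raw, criterion_id)
}

#' Construct an external score table from a data frame
#'
#' @param scores Data frame with columns `gene`, `score`.
#' @param criterion_id Integer, 1, 2 or 3 (fixes the direction).
#' @return An `external_scores` tibble.
#' @export
external_scores <- function(scores, criterion_id) {
  if (!criterion_id %in% 1:3) {
    abort("criterion_id must be 1, 2 or 3 for external score tables.")
  }
  direction <- if (criterion_id == 2L) "lower_is_better" else "higher_is_better"
  out <- as_tibble(scores)[, c("gene", "score")]
  attr(out, "criterion_id") <- as.integer(criterion_id)
  attr(out, "direction") <- direction
  class(out) <- c("external_scores", class(out))
  out
}

#' Write a priority report
#'
#' Writes the final gene priority table as TSV with columns `gene`,
#' `rank1`..`rank10`, `average_rank`, sorted ascending by average rank
#' with alphabetical order within ties. Values round-trip losslessly
#' through [read_priority_report()].
#'
#' @param report A priority report, as returned by
#'   [aggregate_average_rank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_priority_report <- function(report, path) {
  if (nrow(report) == 0L) abort("Priority report is empty.")
  out <- arrange(as_tibble(report), .data$average_rank, .data$gene)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a priority report written by [write_priority_report()]
#'
#' @param path Path to the TSV file.
#' @return A `priority_report` tibble.
#' @export
read_priority_report <- function(path) {
  out <- readr::read_tsv(
    path,
    show_col_types = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(),
      .default = readr::col_double()
    )
  )
  needed <- c("gene", paste0("rank", 1:10), "average_rank")
  if (!all(needed %in% names(out))) {
    abort(sprintf("Priority report must have columns: %s.", paste(needed, collapse = ", ")))
  }
  new_priority_report(out[needed])
}

#' Read a comorbid-disease list (one disease name per line)
#'
#' @param path Path to the file; `#`-prefixed lines are ignored.
#' @return Character vector of disease names.
#' @export
read_comorbid_diseases <- function(path) {
  lines <- trimws(readr::read_lines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
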