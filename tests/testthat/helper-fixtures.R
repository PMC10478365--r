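# quick constructors for small typed networks used across tests

gene_edges <- function(pairs, itype = "associative") {
  # pairs: character vector "A-B"
  sp <- strsplit(pairs, "-", fixed = TRUE)
  tibble::tibble(
    source = vapply(sp, `[`, "", 1),
    source_class = "gene",
    target = vapply(sp, `[`, "", 2),
    target_class = "gene",
    itype = itype
  )
}

gene_net <- function(pairs, itype = "associative", name = "toy") {
  assoc_network(gene_edges(pairs, itype), name = name)
}

# random simple gene-only network on n nodes, edge probability p
random_gene_net <- function(n, p, seed) {
  set.seed(seed)
  genes <- sprintf("V%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  edges <- tibble::tibble(
    source = genes[pairs[, 1]], source_class = "gene",
    target = genes[pairs[, 2]], target_class = "gene",
    itype = "associative"
  )
  assoc_network(edges, nodes = tibble::tibble(id = genes, node_class = "gene"))
}

# small annotation table: list of process_id -> gene vector
make_annotations <- function(process_genes) {
  dplyr::bind_rows(lapply(names(process_genes), function(p) {
    tibble::tibble(process_id = p, process_name = NA_character_, gene = process_genes[[p]])
  }))
}

make_snp_row <- function(snp_id, gene, tissues, maf, diseases = character(0),
                         gene_length_nt = 100000L) {
  tibble::tibble(
    snp_id = snp_id, gene = gene,
    eqtl_tissues = list(tissues), maf = maf,
    associated_diseases = list(diseases),
    gene_length_nt = gene_length_nt
  )
}
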