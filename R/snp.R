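#' Filter an SNP catalog to qualifying SNPs
#'
#' A qualifying SNP ("list Y") alters expression of its gene in the
#' target tissue (brain by default) and has a minor allele frequency of
#' at least `maf_min` (5% by default; the boundary is inclusive).
#'
#' @param catalog SNP catalog tibble from [read_snp_catalog()].
#' @param tissue Required eQTL tissue (default `"brain"`); matched
#'   case-insensitively.
#' @param maf_min Minimum minor allele frequency, in (0, 1).
#' @return A tibble of qualifying SNP rows with attributes `tissue` and
#'   `maf_min`, class `qualifying_snps`.
#' @export
filter_qualifying_snps <- function(catalog, tissue = "brain", maf_min = 0.05) {
  assert_scalar_number(maf_min, "maf_min", lower = 0, upper = 1)
  if (maf_min <= 0 || maf_min >= 1) abort("`maf_min` must lie strictly within (0, 1).")
  catalog <- as_tibble(catalog)
  keep <- purrr::map_lgl(catalog$eqtl_tissues, function(ts) {
    tolower(tissue) %in% tolower(ts)
  }) & catalog$maf >= maf_min
  out <- catalog[keep, , drop = FALSE]
  attr(out, "tissue") <- tissue
  attr(out, "maf_min") <- maf_min
  class(out) <- c("qualifying_snps", class(out))
  out
}

#' Binary SNP-based criterion ranks (criteria 8-10)
#'
#' Criterion 8 gives rank 1 to every candidate gene carrying at least
#' one qualifying SNP; criteria 9 and 10 additionally require the SNP to
#' be associated with a whitelisted disease (the two studied diseases
#' for criterion 9, the comorbid-disease list for criterion 10). Every
#' other gene receives the maximal rank `N`, the size of the candidate
#' list, so these criteria carry extra weight in the average.
#'
#' @param candidates Candidate gene symbols (list X).
#' @param qualifying A `qualifying_snps` table from
#'   [filter_qualifying_snps()].
#' @param criterion_id 8, 9 or 10.
#' @param disease_whitelist Disease names; ignored for criterion 8,
#'   required non-empty for criteria 9 and 10. Matched
#'   case-insensitively.
#' @return A tibble (`gene`, `rank`, `evidence_snp_ids`) where `rank`
#'   is 1 or `length(candidates)`.
#' @export
binary_snp_criterion <- function(candidates, qualifying, criterion_id,
                                 disease_whitelist = character(0)) {
  if (!criterion_id %in% 8:10) abort("criterion_id must be 8, 9 or 10.")
  if (length(candidates) == 0L) abort("Candidate list is empty.")
  if (criterion_id %in% c(9L, 10L) && length(disease_whitelist) == 0L) {
    abort(sprintf("Criterion %d needs a non-empty disease whitelist.", criterion_id))
  }
  n_max <- length(candidates)
  qualifying <- as_tibble(qualifying)
  if (criterion_id != 8L) {
    wl <- tolower(disease_whitelist)
    hit <- purrr::map_lgl(qualifying$associated_diseases, function(d) {
      any(tolower(d) %in% wl)
    })
    qualifying <- qualifying[hit, , drop = FALSE]
  }
  by_gene <- split(qualifying$snp_id, sym_key(qualifying$gene))
  evidence <- purrr::map(sym_key(candidates), function(k) {
    v <- by_gene[[k]]
    if (is.null(v)) character(0) else sort(unique(v))
  })
  tibble(
    gene = candidates,
    rank = if_else(lengths(evidence) > 0L, 1, as.numeric(n_max)),
    evidence_snp_ids = evidence
  )
}

#' Qualifying-SNP density of a gene
#'
#' The number of qualifying SNPs per 1000 nucleotides of gene length.
#' Genes exceeding about 7 SNPs per 1000 nt are the densest seen in
#' brain-eQTL catalogs and are worth flagging.
#'
#' @param gene Gene symbol.
#' @param qualifying A `qualifying_snps` table.
#' @param gene_length_nt Gene length in nucleotides; if `NULL`, taken
#'   from the catalog rows of the gene.
#' @return SNPs per 1000 nucleotides (0 when the gene has no qualifying
#'   SNP).
#' @export
snp_density <- function(gene, qualifying, gene_length_nt = NULL) {
  qualifying <- as_tibble(qualifying)
  rows <- qualifying[sym_key(qualifying$gene) == sym_key(gene), , drop = FALSE]
  if (is.null(gene_length_nt)) {
    if (nrow(rows) == 0L) {
      abort(sprintf("Gene '%s' has no catalog rows; pass gene_length_nt explicitly.", gene))
    }
    gene_length_nt <- rows$gene_length_nt[1]
  }
  if (length(gene_length_nt) != 1L || is.na(gene_length_nt) || gene_length_nt <= 0) {
    abort("gene_length_nt must be a single positive number.")
  }
  nrow(rows) * 1000 / gene_length_nt
}
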