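#' Build the complete comorbidity network of two diseases
#'
#' Genes associated with each disease are collected as the union over
#' sources (curated network database and GeneCards-style lists); the
#' complete comorbidity network is the subgraph of the global network
#' induced on entities associated with BOTH diseases simultaneously.
#' Gene and protein nodes sharing a symbol count as one entity; symbol
#' matching is case-insensitive.
#'
#' @param assoc Disease-gene association table, see
#'   [read_disease_genes()].
#' @param disease_a,disease_b Names of the two diseases.
#' @param global_net The global [assoc_network()] from which the
#'   subgraph is induced.
#' @return An [assoc_network()] on the shared entities (isolated shared
#'   nodes are kept). An empty intersection yields an empty network with
#'   a warning.
#' @export
intersect_disease_networks <- function(assoc, disease_a, disease_b, global_net) {
  assoc <- as_tibble(assoc)
  for (d in c(disease_a, disease_b)) {
    if (!d %in% assoc$disease) {
      abort(sprintf("Disease '%s' absent from the association table.", d))
    }
  }
  genes_a <- unique(sym_key(assoc$gene[assoc$disease == disease_a]))
  genes_b <- unique(sym_key(assoc$gene[assoc$disease == disease_b]))
  shared <- intersect(genes_a, genes_b)
  if (length(shared) == 0L) {
    warn(sprintf("No genes shared between '%s' and '%s'.", disease_a, disease_b))
  }
  induce_on_entities(
    global_net, shared,
    name = sprintf("complete %s/%s network", disease_a, disease_b)
  )
}

induce_on_entities <- function(net, entity_keys, name) {
  nodes <- filter(net$nodes, sym_key(.data$id) %in% entity_keys)
  edges <- filter(
    net$edges,
    sym_key(.data$source) %in% entity_keys & sym_key(.data$target) %in% entity_keys
  )
  if (nrow(nodes) == 0L) {
    return(structure(
      list(
        nodes = tibble(id = character(0), node_class = character(0)),
        edges = tibble(
          source = character(0), source_class = character(0),
          target = character(0), target_class = character(0),
          itype = character(0)
        ),
        name = name
      ),
      class = "assoc_network"
    ))
  }
  assoc_network(edges, nodes = nodes, name = name)
}

#' Extract the genetic regulatory subnetwork
#'
#' Keeps only the edges whose type is regulatory (by default every type
#' except generic associations and protein-protein interactions) and
#' drops nodes left isolated. The result may be disconnected.
#'
#' @param net An [assoc_network()].
#' @param types Character vector of edge types to keep; defaults to
#'   [regulatory_types()].
#' @return An [assoc_network()].
#' @export
extract_regulatory_subnetwork <- function(net, types = regulatory_types()) {
  check_itype(types)
  edges <- filter(net$edges, .data$itype %in% types)
  assoc_network(edges, name = paste0(net$name, " (regulatory)"))
}

#' Summarize a typed network
#'
#' Counts nodes by class and edges by interaction type; the total always
#' equals the sum of the per-type counts.
#'
#' @param net An [assoc_network()].
#' @return A list with `n_gene_nodes`, `n_protein_nodes`,
#'   `per_type_edge_counts` (a tibble `itype`, `n` covering all seven
#'   types) and `total_edges`.
#' @export
summarize_network <- function(net) {
  per_type <- tibble(itype = interaction_types()) |>
    left_join(count(net$edges, .data$itype), by = "itype") |>
    mutate(n = if_else(is.na(.data$n), 0L, .data$n))
  list(
    name = net$name,
    n_gene_nodes = sum(net$nodes$node_class == "gene"),
    n_protein_nodes = sum(net$nodes$node_class == "protein"),
    per_type_edge_counts = per_type,
    total_edges = sum(per_type$n)
  )
}

#' Write a network summary as TSV
#'
#' @param summary A summary from [summarize_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_summary <- function(summary, path) {
  out <- bind_rows(
    summary$per_type_edge_counts,
    tibble(itype = "TOTAL", n = summary$total_edges)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Compute entity-level network centralities
#'
#' The typed network is collapsed to a simple undirected graph over gene
#' entities (see [entity_graph()]); for each entity the function returns
#' the raw degree, the normalized degree centrality
#' \eqn{DC = k / (N - 1)}, the betweenness centrality
#' \eqn{BC(n) = \sum_{s \ne n \ne t} \sigma_{st}(n) / \sigma_{st}}
#' normalized by \eqn{(N-1)(N-2)/2} so it lies in \[0, 1\] (pairs in
#' different components contribute 0), and the neighborhood cohesion
#' \eqn{CC = 2 e_n / (k_n (k_n - 1))} -- the fraction of connected
#' pairs among the node's neighbors, 0 when the degree is below 2.
#'
#' @param net An [assoc_network()].
#' @return A tibble with columns `entity`, `degree_raw`, `dc`, `bc`,
#'   `cc`, class `centrality_tbl`.
#' @export
compute_centralities <- function(net) {
  g <- entity_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) abort("Centralities are undefined for networks with fewer than 2 entities.")
  deg <- igraph::degree(g)
  bc_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  bc <- if (n > 2L) bc_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  out <- tibble(
    entity = igraph::V(g)$name,
    degree_raw = as.integer(unname(deg)),
    dc = unname(deg) / (n - 1),
    bc = as.numeric(bc),
    cc = as.numeric(cc)
  ) |>
    arrange(.data$entity)
  class(out) <- c("centrality_tbl", class(out))
  out
}

#' Cross-talk specificity (CTS)
#'
#' The ratio \eqn{CTS = K_i / M_i} of the number of links a gene has in
#' an analyzed subnetwork to the number of links it has in the global
#' network. Vectorized over genes.
#'
#' @param k_links Links in the analyzed network (\eqn{K_i}).
#' @param m_links Links in the global network (\eqn{M_i}); must be
#'   positive.
#' @return Numeric vector of CTS values in \[0, 1\].
#' @export
#' @examples
#' cross_talk_specificity(5, 50)
cross_talk_specificity <- function(k_links, m_links) {
  if (length(k_links) != length(m_links)) {
    abort("k_links and m_links must have equal length.")
  }
  if (any(m_links <= 0)) abort("CTS is undefined when the global link count is 0.")
  if (any(k_links < 0)) abort("Link counts must be nonnegative.")
  if (any(k_links > m_links)) {
    abort("A gene cannot have more links in a subnetwork than in the global network.")
  }
  k_links / m_links
}

#' Cross-talk specificity of every entity of a subnetwork
#'
#' @param net Analyzed subnetwork.
#' @param global_net Global network containing it.
#' @return A tibble `entity`, `k_links`, `m_links`, `cts`.
#' @export
network_cts <- function(net, global_net) {
  g_sub <- entity_graph(net)
  g_glob <- entity_graph(global_net)
  entities <- igraph::V(g_sub)$name
  missing <- setdiff(sym_key(entities), sym_key(igraph::V(g_glob)$name))
  if (length(missing) > 0L) {
    abort("Analyzed network contains entities absent from the global network.")
  }
  glob_names <- igraph::V(g_glob)$name
  idx <- match(sym_key(entities), sym_key(glob_names))
  k <- as.integer(igraph::degree(g_sub))
  m <- as.integer(igraph::degree(g_glob)[idx])
  tibble(
    entity = entities, k_links = k, m_links = m,
    cts = cross_talk_specificity(k, m)
  ) |>
    arrange(.data$entity)
}

#' Detect hub genes
#'
#' Hubs are entities whose betweenness, neighborhood cohesion and degree
#' all clear the cutoffs: `bc >= bc_min`, `cc >= cc_min` and
#' `degree_raw > degree_gt` (the degree bound is strict, mirroring the
#' conventional "> 40" cutoff; the other two are inclusive).
#'
#' @param records A centrality table from [compute_centralities()].
#' @param bc_min,cc_min,degree_gt Cutoffs; defaults 0.005, 0.2 and 40.
#' @return Character vector of hub entity symbols.
#' @export
detect_hubs <- function(records, bc_min = 0.005, cc_min = 0.2, degree_gt = 40L) {
  assert_scalar_number(bc_min, "bc_min", lower = 0)
  assert_scalar_number(cc_min, "cc_min", lower = 0)
  assert_scalar_number(degree_gt, "degree_gt", lower = 0)
  records |>
    filter(.data$bc >= bc_min, .data$cc >= cc_min, .data$degree_raw > degree_gt) |>
    pull("entity")
}
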