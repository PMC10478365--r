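#' Construct a typed association network
#'
#' A typed gene/protein association network holds an edge table whose
#' rows are interactions `(source, source_class, target, target_class,
#' itype)` and a node table `(id, node_class)`. A symbol may appear both
#' as a gene node and as a protein node; the two are distinct nodes but
#' are merged into a single "gene entity" for prioritization (see
#' [entity_graph()]). Parallel edges of different types are kept;
#' exact duplicates (same endpoints, classes and type) are collapsed to
#' one.
#'
#' @param edges A data frame with columns `source`, `source_class`,
#'   `target`, `target_class`, `itype`. Classes must be `"gene"` or
#'   `"protein"`; `itype` must be one of [interaction_types()].
#' @param nodes Optional data frame with columns `id`, `node_class`
#'   adding nodes beyond those induced by the edges (e.g. isolated
#'   nodes).
#' @param name Network name used in printing and summaries.
#'
#' @return An object of class `assoc_network`: a list with tibbles
#'   `nodes` and `edges` and the `name`.
#' @export
#' @examples
#' net <- assoc_network(
#'   tibble::tibble(
#'     source = "TNF", source_class = "protein",
#'     target = "IL6", target_class = "gene",
#'     itype = "expression_regulation"
#'   ),
#'   name = "toy"
#' )
#' net
assoc_network <- function(edges, nodes = NULL, name = "network") {
  edges <- as_tibble(edges)
  needed <- c("source", "source_class", "target", "target_class", "itype")
  missing_cols <- setdiff(needed, names(edges))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`edges` lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  edges <- edges[needed]
  bad_class <- setdiff(
    unique(c(edges$source_class, edges$target_class)),
    c("gene", "protein")
  )
  if (length(bad_class) > 0L && nrow(edges) > 0L) {
    abort(sprintf(
      "Node classes must be 'gene' or 'protein', got: %s.",
      paste(bad_class, collapse = ", ")
    ))
  }
  check_itype(edges$itype)
  edges <- distinct(edges)

  induced <- bind_rows(
    tibble(id = edges$source, node_class = edges$source_class),
    tibble(id = edges$target, node_class = edges$target_class)
  )
  if (!is.null(nodes)) {
    nodes <- as_tibble(nodes)
    if (!all(c("id", "node_class") %in% names(nodes))) {
      abort("`nodes` must have columns `id` and `node_class`.")
    }
    induced <- bind_rows(induced, nodes[, c("id", "node_class")])
  }
  nodes <- distinct(induced)
  if (any(!nzchar(nodes$id))) {
    abort("Node ids must be non-empty.")
  }

  structure(
    list(nodes = nodes, edges = edges, name = name),
    class = "assoc_network"
  )
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf(
    "<assoc_network '%s'> %d nodes (%d gene, %d protein), %d edges\n",
    x$name, nrow(x$nodes),
    sum(x$nodes$node_class == "gene"),
    sum(x$nodes$node_class == "protein"),
    nrow(x$edges)
  ))
  invisible(x)
}

#' Entities of a network
#'
#' The distinct gene entities (symbols, case-insensitively merged across
#' gene and protein nodes) of a network, with first-seen casing
#' preserved.
#'
#' @param net An [assoc_network()].
#' @return Character vector of entity symbols, sorted.
#' @export
network_entities <- function(net) {
  ids <- net$nodes$id
  sort(ids[!duplicated(sym_key(ids))])
}

#' Collapse a typed network to a simple undirected entity graph
#'
#' Gene and protein nodes sharing a symbol are merged into one entity;
#' edge types and directions are dropped; parallel edges and self-loops
#' are removed. This is the graph on which centralities are computed:
#' priority tables rank symbols, not gene/protein node classes.
#'
#' @param net An [assoc_network()].
#' @return An undirected simple [igraph::graph] whose vertex names are
#'   entity symbols.
#' @export
entity_graph <- function(net) {
  entities <- network_entities(net)
  canon <- setNames(entities, sym_key(entities))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(entities), name = entities)
  if (nrow(net$edges) > 0L) {
    from <- canon[sym_key(net$edges$source)]
    to <- canon[sym_key(net$edges$target)]
    keep <- from != to
    if (any(keep)) {
      g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
    }
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}
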