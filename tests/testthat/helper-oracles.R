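# Independent brute-force oracles. These deliberately avoid the code
# paths (igraph, phyper, p.adjust) used by the implementation.

# adjacency matrix of the entity-level simple graph of a network
entity_adjacency <- function(net) {
  ids <- net$nodes$id
  entities <- sort(ids[!duplicated(toupper(ids))])
  n <- length(entities)
  adj <- matrix(0L, n, n, dimnames = list(entities, entities))
  if (nrow(net$edges) > 0L) {
    s <- match(toupper(net$edges$source), toupper(entities))
    t <- match(toupper(net$edges$target), toupper(entities))
    keep <- s != t
    adj[cbind(s[keep], t[keep])] <- 1L
    adj[cbind(t[keep], s[keep])] <- 1L
  }
  adj
}

# BFS distances and shortest-path counts from source s (index)
bf_sp_counts <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  d <- 0
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] == 1L)
      for (w in nb) {
        if (is.infinite(dist[w])) {
          dist[w] <- d + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == d + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  list(dist = dist, sigma = sigma)
}

# normalized betweenness by direct enumeration over all (s, t) pairs:
# sigma_st(n) = sigma_sn * sigma_nt when d(s,n) + d(n,t) = d(s,t);
# disconnected pairs contribute 0
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  sp <- lapply(seq_len(n), function(s) bf_sp_counts(adj, s))
  bc <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      d_st <- sp[[s]]$dist[t]
      if (is.infinite(d_st)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (sp[[s]]$dist[v] + sp[[v]]$dist[t] == d_st) {
          bc[v] <- bc[v] + sp[[s]]$sigma[v] * sp[[v]]$sigma[t] / sp[[s]]$sigma[t]
        }
      }
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else rep(0, n)
}

# neighborhood cohesion by direct neighbor-pair counting
bf_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}

# hypergeometric upper tail by exhaustive enumeration of all queries of
# size n from a universe of size N with K annotated genes: the fraction
# of draws whose overlap is >= k
enum_hyper_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Benjamini-Hochberg step-up by the textbook formula
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
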