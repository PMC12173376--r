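# Independent oracles used to cross-check the package implementations.
# These deliberately use different primitives than the code under test.

# exact upper-tail hypergeometric by direct enumeration of choose() products
hyper_enum_oracle <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by explicit sort / cumulative minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# betweenness by exhaustive enumeration of all shortest paths (tiny graphs)
# adj: symmetric logical/0-1 matrix with node names
betweenness_oracle <- function(adj) {
  nodes <- rownames(adj)
  n <- length(nodes)
  bc <- stats::setNames(numeric(n), nodes)
  all_paths <- function(s, t) {
    # BFS distances from s
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0))
        if (dist[w] == Inf) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    # backtrack all shortest s->t paths
    walk <- function(v) {
      if (v == s) return(list(s))
      preds <- which(adj[, v] > 0 & dist == dist[v] - 1)
      out <- list()
      for (p in preds)
        for (pre in walk(p)) out[[length(out) + 1]] <- c(pre, v)
      out
    }
    walk(t)
  }
  if (n < 3) return(bc)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    for (p in paths) {
      internal <- setdiff(p, c(s, t))
      bc[internal] <- bc[internal] + 1 / length(paths)
    }
  }
  bc
}

# small deterministic expression fixture: 6 genes x (3+3), closed-form checks
fixture_6x6 <- function() {
  m <- rbind(
    c(5.0, 5.2, 4.8, 3.0, 3.1, 2.9),
    c(8.0, 8.0, 8.0, 8.0, 8.0, 8.0),
    c(6.1, 5.9, 6.0, 6.5, 6.4, 6.6),
    c(10.0, 9.5, 10.5, 7.0, 7.5, 6.5),
    c(4.2, 4.4, 4.0, 4.3, 4.1, 4.5),
    c(7.7, 7.1, 7.4, 9.0, 9.6, 9.3))
  dimnames(m) <- list(paste0("GENE", 1:6), paste0("S", 1:6))
  expression_study(m, stats::setNames(rep(c("CASE", "CONTROL"), each = 3),
                                      colnames(m)))
}

small_spec <- function(seed = 1, ...) {
  args <- list(n_genes = 2000, pn_size = 250,
               pathway_sizes = c(ALP = 80, UPS = 70, EXTRACELLULAR = 50,
                                 PROTEOSTASIS_REGULATION = 50),
               group_sizes = c(KINASE = 60, TF = 120, ION_CHANNEL = 30),
               k = 50, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_spec, args)
}
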