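# Brute-force oracles for the controllability module. These enumerate
# matchings exhaustively and stay independent of the package's
# matching-based implementation.

# Maximum matching of the bipartite lift of a directed edge list, by
# exhaustive branch-and-bound over left (out-copy) vertices.
oracle_max_matching <- function(nodes, edges) {
  nodes <- sort(nodes)
  if (nrow(edges) == 0) return(0L)
  adj <- lapply(nodes, function(u) sort(unique(edges$to[edges$from == u])))
  n_left <- length(adj)
  rec <- function(i, used) {
    if (i > n_left) return(0L)
    best <- rec(i + 1L, used)
    for (v in adj[[i]]) {
      if (!(v %in% used)) {
        best <- max(best, 1L + rec(i + 1L, c(used, v)))
      }
    }
    best
  }
  rec(1L, character(0))
}

oracle_mdns <- function(nodes, edges) {
  max(length(nodes) - oracle_max_matching(nodes, edges), 1L)
}

oracle_critical <- function(nodes, edges) {
  base <- oracle_mdns(nodes, edges)
  nodes <- sort(nodes)
  crit <- vapply(nodes, function(v) {
    keep <- edges$from != v & edges$to != v
    oracle_mdns(setdiff(nodes, v), edges[keep, , drop = FALSE]) > base
  }, logical(1))
  nodes[crit]
}

# Random directed graph on n nodes with edge probability p (no self-loops).
random_digraph <- function(n, p) {
  nodes <- letters[seq_len(n)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes, edges = tibble::tibble(from = pairs$from[keep],
                                             to = pairs$to[keep]))
}

as_network <- function(g) {
  gene_network(g$edges, nodes = g$nodes, convention = "as_given")
}

# Adjusted Rand index between two label vectors (closed form from the
# pair-counting contingency table).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
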