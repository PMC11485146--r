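#' Bipartite lift of a directed network
#'
#' Standard construction for maximum-matching-based structural
#' controllability: each node contributes an out-copy (left part) and an
#' in-copy (right part), and each directed edge u -> v becomes the bipartite
#' edge (u+, v-). The size of a maximum matching of this graph determines the
#' minimum driver node set.
#'
#' @param net A `gene_network`.
#' @return A tibble with columns `out_copy`, `in_copy`.
#' @export
bipartite_lift <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(net$edges) == 0) {
    return(tibble::tibble(out_copy = character(0), in_copy = character(0)))
  }
  tibble::tibble(out_copy = paste0(net$edges$from, "+"),
                 in_copy = paste0(net$edges$to, "-"))
}

# Maximum-cardinality matching of the bipartite lift, deterministic under
# sorted node order. Returns list(size, matched_in): matched_in maps each
# matched in-copy (node name, no suffix) to its out-copy partner.
lift_matching <- function(nodes, edges) {
  nodes <- sort(nodes)
  if (nrow(edges) == 0) {
    return(list(size = 0L, matched_in = character(0)))
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  vertices <- data.frame(
    name = c(paste0(nodes, "+"), paste0(nodes, "-")),
    type = rep(c(FALSE, TRUE), each = length(nodes))
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0(edges$from, "+"), to = paste0(edges$to, "-")),
    directed = FALSE, vertices = vertices
  )
  m <- igraph::max_bipartite_match(g, types = igraph::V(g)$type)
  mt <- m$matching
  in_names <- paste0(nodes, "-")
  matched <- mt[in_names]
  matched <- matched[!is.na(matched)]
  names(matched) <- sub("-$", "", names(matched))
  list(size = as.integer(m$matching_size), matched_in = matched)
}

#' Minimum driver node set of a directed network
#'
#' Computes the MDNS size `max(N - |M*|, 1)` where `M*` is a maximum matching
#' of the bipartite lift, together with one witness driver set: the nodes
#' whose in-copies are unmatched. When the matching is perfect the network
#' still needs one external input, and the first node in sorted order is
#' reported as the witness driver.
#'
#' @param net A `gene_network` with at least one node.
#' @return A list with `size` (positive integer), `drivers` (character
#'   vector, length `size`), and `matching_size`.
#' @export
mdns <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  if (n == 0) stop("network has no nodes", call. = FALSE)
  m <- lift_matching(net$nodes, net$edges)
  unmatched <- setdiff(sort(net$nodes), names(m$matched_in))
  if (length(unmatched) == 0) {
    drivers <- sort(net$nodes)[1]
  } else {
    drivers <- unmatched
  }
  list(size = max(n - m$size, 1L), drivers = drivers,
       matching_size = m$size)
}

#' MDNS size of a directed network
#' @param net A `gene_network`.
#' @return A positive integer.
#' @export
mdns_size <- function(net) mdns(net)$size

delete_node <- function(net, v) {
  keep <- net$edges$from != v & net$edges$to != v
  gene_network(net$edges[keep, , drop = FALSE],
               nodes = setdiff(net$nodes, v),
               convention = net$convention)
}

#' Classify critical nodes of a network
#'
#' For each node `v`, the node and all incident edges are removed and the
#' MDNS of the remaining network recomputed; `v` is critical when the MDNS
#' size strictly increases. The result is deterministic for a given edge set
#' regardless of input order.
#'
#' @param net A `gene_network` with at least 2 nodes.
#' @return A tibble of class `control_result` with columns `node`, `class`
#'   (`critical` / `non_critical`) and `mdns_after` (MDNS size of the
#'   node-deleted network); attributes `mdns_size` and `drivers` describe the
#'   intact network.
#' @export
critical_nodes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (length(net$nodes) < 2) {
    stop("need >= 2 nodes to classify criticality", call. = FALSE)
  }
  base <- mdns(net)
  after <- vapply(sort(net$nodes),
                  function(v) mdns(delete_node(net, v))$size,
                  integer(1))
  out <- tibble::tibble(
    node = names(after),
    class = ifelse(after > base$size, "critical", "non_critical"),
    mdns_after = unname(after)
  )
  attr(out, "mdns_size") <- base$size
  attr(out, "drivers") <- base$drivers
  class(out) <- c("control_result", class(out))
  out
}

#' @exportS3Method base::print
print.control_result <- function(x, ...) {
  cat(sprintf("<control_result> MDNS size %d, %d/%d critical nodes\n",
              attr(x, "mdns_size"), sum(x$class == "critical"), nrow(x)))
  NextMethod()
}

#' Critical nodes as a character vector
#' @param result A `control_result` from [critical_nodes()].
#' @return Character vector of critical node names.
#' @export
critical_set <- function(result) {
  result$node[result$class == "critical"]
}
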