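#' Pairwise Pearson correlations among a gene panel
#'
#' Computes, for every unordered pair of panel genes, the Pearson correlation
#' of their expression across samples and a two-sided p-value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Genes with zero variance across samples are excluded up front
#' with a message (their correlations are undefined).
#'
#' @param x An [expression_matrix()] on the log2 scale.
#' @param genes Character vector or [gene_set()] restricting the panel
#'   (default: all genes in the matrix).
#' @param samples Optional sample ids to use (default: all tumour samples if
#'   any are labelled, otherwise all samples).
#' @return A tibble with columns `gene_a`, `gene_b` (canonical
#'   `gene_a < gene_b`), `pcc`, `p`.
#' @export
pairwise_pcc <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  if (is.null(samples)) {
    tum <- x$samples$sample_id[x$samples$condition == "tumour"]
    samples <- if (length(tum) > 0) tum else x$samples$sample_id
  }
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- genes %||% rownames(x$values)
  genes <- intersect(genes, rownames(x$values))
  v <- x$values[genes, samples, drop = FALSE]
  n <- ncol(v)
  if (n < 3) stop("need >= 3 samples for correlation p-values", call. = FALSE)
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " zero-variance genes from correlation")
    v <- v[sds > 0, , drop = FALSE]
  }
  if (nrow(v) < 2) {
    return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                          pcc = numeric(0), p = numeric(0)))
  }
  r <- cor(t(v))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rr <- r[idx]
  # clamp rounding spill beyond [-1, 1] before the t transform
  rr <- pmin(pmax(rr, -1), 1)
  tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, 0))
  p <- ifelse(is.infinite(tt) | (1 - rr^2) <= 0,
              0, 2 * pt(-abs(tt), df = n - 2))
  ga <- rownames(r)[idx[, 1]]
  gb <- rownames(r)[idx[, 2]]
  tibble::tibble(gene_a = pmin(ga, gb), gene_b = pmax(ga, gb),
                 pcc = unname(rr), p = unname(p))
}

#' Construct a gene network
#'
#' Internal-facing constructor for a directed gene network stored as an edge
#' tibble plus a node vector. Under the `antiparallel_pairs` convention each
#' unordered interaction appears as two directed edges with equal attributes.
#'
#' @param edges Tibble with columns `from`, `to` and optional attributes
#'   (`pcc`, `adj_p`).
#' @param nodes Character vector of node names (default: edge endpoints).
#' @param convention `"antiparallel_pairs"` or `"as_given"`.
#' @return A `gene_network` object.
#' @export
gene_network <- function(edges, nodes = NULL,
                         convention = c("antiparallel_pairs", "as_given")) {
  convention <- match.arg(convention)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 && any(edges$from == edges$to)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  nodes <- sort(unique(c(nodes %||% character(0), edges$from, edges$to)))
  edges <- dplyr::distinct(dplyr::arrange(edges, .data$from, .data$to))
  structure(list(nodes = nodes, edges = edges, convention = convention),
            class = "gene_network")
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d directed edges (%s)\n",
              length(x$nodes), nrow(x$edges), x$convention))
  invisible(x)
}

#' Build the correlation gene regulatory network
#'
#' Takes the pairwise correlation table over differentially expressed genes
#' (already restricted to genes present in the interaction database),
#' BH-adjusts the edge p-values over all tested pairs, keeps pairs with
#' `adj_p <= alpha`, intersects the survivors with the interaction database,
#' and expands each surviving unordered pair into an antiparallel directed
#' pair. Nodes are the endpoints of surviving edges; isolated genes are
#' dropped.
#'
#' @param pcc_table Tibble from [pairwise_pcc()].
#' @param db An [interaction_db()].
#' @param alpha Edge FDR threshold (default 0.05).
#' @return A `gene_network` with edge attributes `pcc` and `adj_p`.
#' @export
build_network <- function(pcc_table, db, alpha = 0.05) {
  stopifnot(all(c("gene_a", "gene_b", "pcc", "p") %in% names(pcc_table)))
  tab <- tibble::as_tibble(pcc_table)
  tab$adj_p <- bh_adjust(tab$p)
  kept <- dplyr::filter(tab, .data$adj_p <= alpha)
  kept <- dplyr::semi_join(kept, db, by = c("gene_a", "gene_b"))
  if (nrow(kept) == 0) {
    warning("no edges survive the FDR filter and database refinement")
    return(gene_network(tibble::tibble(from = character(0), to = character(0),
                                       pcc = numeric(0), adj_p = numeric(0))))
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(from = kept$gene_a, to = kept$gene_b,
                   pcc = kept$pcc, adj_p = kept$adj_p),
    tibble::tibble(from = kept$gene_b, to = kept$gene_a,
                   pcc = kept$pcc, adj_p = kept$adj_p)
  )
  gene_network(edges, convention = "antiparallel_pairs")
}

#' Edge list of a network as a tibble
#' @param net A `gene_network`.
#' @return The edge tibble (`from`, `to`, attributes).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$edges
}
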