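#' Log2(x + 1) transform a count-scale expression matrix
#'
#' @param x An [expression_matrix()] with `scale = "counts"`; applying the
#'   transform twice is an error.
#' @return The matrix on the log2 scale (`scale = "log2"`).
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$scale == "log2") stop("matrix is already log2 transformed", call. = FALSE)
  if (any(x$values < 0)) stop("negative values on the count scale", call. = FALSE)
  expression_matrix(log2(x$values + 1), x$samples, scale = "log2")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment used for every multiple-testing family in
#' the pipeline (per-gene DE tests, per-pair network edge tests). Values are
#' adjusted by rank and returned in the input order, clipped to \[0, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Two-condition differential-expression screen
#'
#' Per-gene tumour-vs-normal comparison on the log2 scale: the effect is the
#' difference of group means (log2 fold change), the p-value comes from a
#' two-sample Welch t-test (a pooled-variance variant is available via
#' `var_equal`), and the family is corrected by Benjamini-Hochberg. A gene is
#' called `up` when `adj_p <= alpha` and `log2fc >= lfc`, `down` when
#' `adj_p <= alpha` and `log2fc <= -lfc`, otherwise `ns`.
#'
#' Degenerate genes with zero variance in both groups get `p = 1` when the
#' group means are equal and `p = 0` when they differ.
#'
#' @param x An [expression_matrix()] on the log2 scale.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param var_equal Use a pooled-variance t-test instead of Welch.
#' @return A tibble with columns `gene_id`, `log2fc`, `p_value`, `adj_p`,
#'   `status`.
#' @export
de_test <- function(x, alpha = 0.05, lfc = 1, var_equal = FALSE) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$scale != "log2") stop("run log_transform() first", call. = FALSE)
  tum <- x$values[, x$samples$condition == "tumour", drop = FALSE]
  nor <- x$values[, x$samples$condition == "normal", drop = FALSE]
  n1 <- ncol(tum); n0 <- ncol(nor)
  if (n1 < 2 || n0 < 2) stop("need >= 2 samples per condition", call. = FALSE)
  m1 <- rowMeans(tum); m0 <- rowMeans(nor)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1)
  v0 <- rowSums((nor - m0)^2) / (n0 - 1)
  diff <- m1 - m0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(diff))
  } else {
    a1 <- v1 / n1; a0 <- v0 / n0
    se <- sqrt(a1 + a0)
    df <- (a1 + a0)^2 / (a1^2 / (n1 - 1) + a0^2 / (n0 - 1))
  }
  p <- ifelse(se > 0,
              2 * pt(-abs(diff / se), df),
              ifelse(diff == 0, 1, 0))
  adj <- bh_adjust(p)
  status <- dplyr::case_when(
    adj <= alpha & diff >= lfc ~ "up",
    adj <= alpha & diff <= -lfc ~ "down",
    TRUE ~ "ns"
  )
  tibble::tibble(gene_id = rownames(x$values), log2fc = unname(diff),
                 p_value = unname(p), adj_p = unname(adj), status = status)
}

#' Select significant differentially expressed genes
#'
#' @param results Tibble from [de_test()].
#' @return A [gene_set()] of genes whose status is `up` or `down`.
#' @export
select_degs <- function(results) {
  sel <- results$gene_id[results$status != "ns"]
  if (length(sel) == 0) {
    warning("no differentially expressed genes at the given thresholds")
    return(structure(list(name = "degs", genes = character(0)),
                     class = "gene_set"))
  }
  gene_set("degs", sel)
}

#' Volcano plot of a differential-expression screen
#'
#' @param results Tibble from [de_test()].
#' @param lfc Fold-change guide lines (default 1).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, lfc = 1) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$adj_p, 1e-300)),
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (tumour - normal)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}
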