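#' Expression matrix container
#'
#' A light container for a genes x samples numeric expression matrix with
#' per-sample condition labels (`tumour` / `normal`), an optional cancer-type
#' label, and a scale tag recording whether values are on the raw count scale
#' or have been log2(x + 1) transformed. The tag makes a double log transform
#' impossible.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns (colnames are sample ids). No missing values.
#' @param condition Data frame with columns `sample_id`, `condition`
#'   (`"tumour"` or `"normal"`) and optionally `cancer_type`. Every column of
#'   `values` must appear exactly once.
#' @param scale One of `"counts"` (non-negative) or `"log2"`.
#'
#' @return An object of class `expr_mat`: a list with elements `values`
#'   (the matrix), `samples` (a tibble of per-sample metadata in column
#'   order) and `scale`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cond <- data.frame(sample_id = paste0("s", 1:4),
#'                    condition = rep(c("tumour", "normal"), each = 2))
#' expression_matrix(m, cond)
expression_matrix <- function(values, condition, scale = c("counts", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    stop("duplicated gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) stop("expression values contain missing entries", call. = FALSE)
  if (scale == "counts" && any(values < 0)) {
    stop("count-scale expression must be non-negative", call. = FALSE)
  }
  condition <- tibble::as_tibble(condition)
  if (!all(c("sample_id", "condition") %in% names(condition))) {
    stop("condition table needs columns `sample_id` and `condition`", call. = FALSE)
  }
  if (!"cancer_type" %in% names(condition)) condition$cancer_type <- NA_character_
  missing <- setdiff(colnames(values), condition$sample_id)
  if (length(missing) > 0) {
    stop("samples absent from condition table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(condition$condition), c("tumour", "normal"))
  if (length(bad) > 0) {
    stop("condition labels must be 'tumour' or 'normal', found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  samples <- condition[match(colnames(values), condition$sample_id),
                       c("sample_id", "condition", "cancer_type")]
  structure(list(values = values, samples = samples, scale = scale),
            class = "expr_mat")
}

#' @exportS3Method base::print
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  tumour: %d, normal: %d\n",
              sum(x$samples$condition == "tumour"),
              sum(x$samples$condition == "normal")))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x An [expression_matrix()].
#' @param genes,samples Character vectors of ids to keep (default: all).
#' @return An `expr_mat` restricted to the requested genes and samples.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  genes <- genes %||% rownames(x$values)
  samples <- samples %||% colnames(x$values)
  missing_g <- setdiff(genes, rownames(x$values))
  if (length(missing_g) > 0) {
    stop("genes not in matrix: ", paste(missing_g, collapse = ", "), call. = FALSE)
  }
  missing_s <- setdiff(samples, colnames(x$values))
  if (length(missing_s) > 0) {
    stop("samples not in matrix: ", paste(missing_s, collapse = ", "), call. = FALSE)
  }
  expression_matrix(x$values[genes, samples, drop = FALSE],
                    x$samples[x$samples$sample_id %in% samples, ],
                    scale = x$scale)
}

#' Tumour-sample expression as a tidy tibble
#'
#' Long-format view used by the stratification and risk-model stages, which
#' operate on tumour samples only.
#'
#' @param x An [expression_matrix()].
#' @param genes Genes to include (default all).
#' @return A tibble with columns `sample_id`, `gene`, `value`.
#' @export
expr_tidy <- function(x, genes = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  genes <- genes %||% rownames(x$values)
  v <- x$values[genes, , drop = FALSE]
  tibble::tibble(
    sample_id = rep(colnames(v), each = nrow(v)),
    gene = rep(rownames(v), times = ncol(v)),
    value = as.vector(v)
  )
}
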