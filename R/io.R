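#' Read an expression matrix with condition labels
#'
#' Reads a genes x samples TSV (first column gene symbols, header row sample
#' ids, tab-separated, '.' decimal) together with a condition TSV mapping
#' every sample to `tumour`/`normal` and a cancer type. Values are taken to
#' be on the count scale (e.g. expected counts from RSEM-style quantification).
#'
#' @param path Path to the expression TSV.
#' @param condition_path Path to the condition TSV with columns `sample_id`,
#'   `condition`, and optionally `cancer_type`.
#' @return An [expression_matrix()] with `scale = "counts"`.
#' @export
read_expression <- function(path, condition_path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
  dup_h <- unique(header[duplicated(header)])
  if (length(dup_h) > 0) {
    stop("duplicated sample ids: ", paste(dup_h, collapse = ", "), call. = FALSE)
  }
  df <- read_tsv_strict(path)
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(m) <- genes
  cond <- read_tsv_strict(condition_path)
  expression_matrix(m, cond, scale = "counts")
}

#' Write an expression matrix and its condition table
#'
#' @param x An [expression_matrix()].
#' @param path Expression TSV destination.
#' @param condition_path Condition TSV destination (skipped if `NULL`).
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, condition_path = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  df <- tibble::as_tibble(x$values, rownames = "gene")
  readr::write_tsv(df, path)
  if (!is.null(condition_path)) readr::write_tsv(x$samples, condition_path)
  invisible(x)
}

#' Read a per-sample survival table
#'
#' Expects columns `sample_id`, `time` (days), `event` (0/1), and optionally
#' `age`, `sex`, `cancer_type`. Samples with missing `time` or `event` are
#' excluded at load with a message stating how many were dropped; missing
#' `age`/`sex` are allowed.
#'
#' @param path Path to the survival TSV.
#' @return A tibble with one row per retained sample.
#' @export
read_survival <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("sample_id", "time", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("survival table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("age", "sex", "cancer_type")) if (!col %in% names(df)) df[[col]] <- NA
  df <- df[, c("sample_id", "time", "event", "age", "sex", "cancer_type")]
  validate_survival(df, drop_incomplete = TRUE)
}

#' Validate a survival table
#'
#' @param df Data frame with at least `sample_id`, `time`, `event`.
#' @param drop_incomplete Drop rows with missing time/event (with a message)
#'   instead of erroring.
#' @return A validated tibble.
#' @export
validate_survival <- function(df, drop_incomplete = FALSE) {
  df <- tibble::as_tibble(df)
  incomplete <- is.na(df$time) | is.na(df$event)
  if (any(incomplete)) {
    if (!drop_incomplete) {
      stop(sum(incomplete), " samples lack time/event", call. = FALSE)
    }
    message("dropping ", sum(incomplete), " samples without survival data")
    df <- df[!incomplete, ]
  }
  if (any(df$time < 0)) stop("negative follow-up times", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stop("duplicated sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a survival table
#' @param df Survival tibble.
#' @param path Destination TSV.
#' @return Invisibly, `df`.
#' @export
write_survival <- function(df, path) {
  readr::write_tsv(validate_survival(df), path)
  invisible(df)
}

#' Construct a named gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols; deduplicated, order of first
#'   appearance kept.
#' @return A `gene_set` object (named character vector wrapper).
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("gene set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene symbols. Genes are deduplicated within each set.
#'
#' @param path Path to the GMT file.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no gene sets in ", path, call. = FALSE)
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, " (need name, description, >=1 gene)",
           call. = FALSE)
    }
    gene_set(fields[[1]], fields[-(1:2)])
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write gene sets to a GMT file
#' @param sets A list of [gene_set()] objects.
#' @param path Destination.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Merge gene sets into one deduplicated list
#'
#' Union of all member genes with duplicates removed, the operation used to
#' assemble a single curated list from several database gene sets.
#'
#' @param sets A non-empty list of [gene_set()] objects.
#' @param name Name for the merged set.
#' @return A [gene_set()] containing each gene once.
#' @export
merge_gene_sets <- function(sets, name = "merged") {
  if (length(sets) == 0) stop("no gene sets to merge", call. = FALSE)
  gene_set(name, unlist(lapply(sets, function(s) s$genes), use.names = FALSE))
}

#' Read an interaction-pair table
#'
#' Two-column (optionally three with a score) TSV of unordered gene pairs
#' emulating a protein-interaction database. Self-pairs are rejected; pairs
#' are canonicalized (alphabetical within pair) and deduplicated.
#'
#' @param path Path to TSV with columns `gene_a`, `gene_b` and optional
#'   `score`.
#' @return A tibble of class `interaction_db` with canonical `gene_a < gene_b`.
#' @export
read_interactions <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("interaction table needs columns gene_a, gene_b", call. = FALSE)
  }
  interaction_db(df)
}

#' Construct an interaction database from a pair table
#'
#' @param df Data frame with `gene_a`, `gene_b`, optional `score`.
#' @return A canonicalized, deduplicated tibble with class `interaction_db`.
#' @export
interaction_db <- function(df) {
  df <- tibble::as_tibble(df)
  if (any(df$gene_a == df$gene_b)) stop("self-pairs are not allowed", call. = FALSE)
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  out <- tibble::tibble(gene_a = a, gene_b = b)
  if ("score" %in% names(df)) out$score <- df$score
  out <- dplyr::distinct(out, .data$gene_a, .data$gene_b, .keep_all = TRUE)
  class(out) <- c("interaction_db", class(out))
  out
}

#' Read a MAF-like somatic mutation table
#'
#' Columns: `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`,
#' `t_alt_count`, `t_depth`, `FILTER`, `REVEL` (missing REVEL allowed).
#'
#' @param path Path to the TSV.
#' @return A tibble of mutation calls with lower-case canonical column names
#'   `gene`, `sample_id`, `variant_classification`, `t_alt_count`, `t_depth`,
#'   `filter_flag`, `revel_score`.
#' @export
read_maf <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
                "t_alt_count", "t_depth", "FILTER")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("MAF table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"REVEL" %in% names(df)) df$REVEL <- NA_real_
  out <- tibble::tibble(
    gene = df$Hugo_Symbol,
    sample_id = df$Tumor_Sample_Barcode,
    variant_classification = df$Variant_Classification,
    t_alt_count = as.integer(df$t_alt_count),
    t_depth = as.integer(df$t_depth),
    filter_flag = df$FILTER,
    revel_score = as.numeric(df$REVEL)
  )
  validate_mutation_calls(out)
}

#' Validate a mutation-call table
#' @param df Tibble in the canonical call layout of [read_maf()].
#' @return The validated tibble.
#' @export
validate_mutation_calls <- function(df) {
  df <- tibble::as_tibble(df)
  if (any(df$t_depth <= 0)) stop("t_depth must be positive", call. = FALSE)
  if (any(df$t_alt_count < 0)) stop("t_alt_count must be non-negative", call. = FALSE)
  if (any(df$t_alt_count > df$t_depth)) {
    stop("t_alt_count exceeds t_depth", call. = FALSE)
  }
  ok <- is.na(df$revel_score) | (df$revel_score >= 0 & df$revel_score <= 1)
  if (!all(ok)) stop("REVEL scores must lie in [0, 1]", call. = FALSE)
  df
}

#' Read a per-gene per-sample CNV class table
#'
#' Columns `gene`, `sample_id`, `cnv_class` with classes among
#' hete_del / homo_del / hete_amp / homo_amp / neutral; one class per
#' (gene, sample).
#'
#' @param path Path to TSV.
#' @return A validated tibble.
#' @export
read_cnv <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("gene", "sample_id", "cnv_class") %in% names(df))) {
    stop("CNV table needs columns gene, sample_id, cnv_class", call. = FALSE)
  }
  classes <- c("hete_del", "homo_del", "hete_amp", "homo_amp", "neutral")
  bad <- setdiff(unique(df$cnv_class), classes)
  if (length(bad) > 0) {
    stop("unknown CNV classes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("gene", "sample_id")])
  if (any(dup)) stop("multiple CNV classes for one (gene, sample)", call. = FALSE)
  tibble::as_tibble(df)
}

read_tsv_strict <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  tibble::as_tibble(df)
}
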