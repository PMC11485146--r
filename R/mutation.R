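#' Default REVEL category cut-points
#'
#' Clinically calibrated thresholds mapping a REVEL ensemble pathogenicity
#' score to evidence categories. Scores at or above `supporting_pathogenic`
#' count as pathogenic evidence; scores at or below `supporting_benign` as
#' benign; the middle band is neither. All cut-points are configurable —
#' they are calibration choices, not properties of the score itself.
#'
#' @return Named list of numeric cut-points.
#' @export
revel_cutpoints <- function() {
  list(strong_benign = 0.016, moderate_benign = 0.183,
       supporting_benign = 0.290,
       supporting_pathogenic = 0.644, moderate_pathogenic = 0.773,
       strong_pathogenic = 0.932)
}

#' Categorise REVEL scores
#'
#' Maps each score to one of `strong_benign`, `moderate_benign`,
#' `supporting_benign`, `uncertain`, `supporting_pathogenic`,
#' `moderate_pathogenic`, `strong_pathogenic`. Boundaries are closed on the
#' pathogenic side for pathogenic cuts (score >= cut) and closed on the
#' benign side for benign cuts (score <= cut); the uncategorised middle band
#' is `uncertain` and is treated as non-pathogenic downstream.
#'
#' @param score Numeric vector in \[0, 1\] (NA allowed, returns NA).
#' @param cuts Cut-point list as from [revel_cutpoints()].
#' @return Character vector of categories.
#' @export
revel_category <- function(score, cuts = revel_cutpoints()) {
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) stop("REVEL scores must lie in [0, 1]", call. = FALSE)
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score >= cuts$strong_pathogenic ~ "strong_pathogenic",
    score >= cuts$moderate_pathogenic ~ "moderate_pathogenic",
    score >= cuts$supporting_pathogenic ~ "supporting_pathogenic",
    score <= cuts$strong_benign ~ "strong_benign",
    score <= cuts$moderate_benign ~ "moderate_benign",
    score <= cuts$supporting_benign ~ "supporting_benign",
    TRUE ~ "uncertain"
  )
}

#' Deleterious variant classifications counted by the SNV filter
#' @return Character vector of MAF variant classifications.
#' @export
deleterious_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Splice_Site", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins")
}

#' Filter somatic SNVs to pathogenic calls
#'
#' Keeps calls that simultaneously (i) carry a deleterious variant
#' classification, (ii) have variant allele frequency
#' `t_alt_count / t_depth` strictly greater than `vaf_min` (computed exactly,
#' no rounding), (iii) are flagged `PASS`, and (iv) have a REVEL category on
#' the pathogenic side (supporting or stronger). The filter is pure: output
#' is a subset of input rows and applying it twice changes nothing.
#'
#' @param calls Mutation-call tibble (layout of [read_maf()]).
#' @param classes Deleterious classifications (default
#'   [deleterious_classes()]).
#' @param vaf_min Strict VAF lower bound (default 0.1).
#' @param cuts REVEL cut-points (default [revel_cutpoints()]).
#' @return The retained calls, with `vaf` and `revel_cat` columns added.
#' @export
filter_snvs <- function(calls, classes = deleterious_classes(),
                        vaf_min = 0.1, cuts = revel_cutpoints()) {
  calls <- validate_mutation_calls(calls)
  calls$vaf <- calls$t_alt_count / calls$t_depth
  calls$revel_cat <- revel_category(calls$revel_score, cuts)
  pathogenic <- c("supporting_pathogenic", "moderate_pathogenic",
                  "strong_pathogenic")
  dplyr::filter(calls,
                .data$variant_classification %in% classes,
                .data$vaf > vaf_min,
                .data$filter_flag == "PASS",
                !is.na(.data$revel_cat) & .data$revel_cat %in% pathogenic)
}

#' Derive per-gene and pooled mutant/wild-type status
#'
#' A (gene, sample) is mutant when a pathogenic SNV was retained for it or
#' its CNV class is a homozygous event (`homo_del` / `homo_amp`);
#' heterozygous CNV events do not count. A sample is pooled-mutant when it
#' is mutant for at least one gene of the tested set.
#'
#' @param snvs Pathogenic calls from [filter_snvs()].
#' @param cnvs CNV tibble (`gene`, `sample_id`, `cnv_class`).
#' @param genes Tested gene set (character or [gene_set()]).
#' @param samples Character vector of all cohort sample ids (needed so that
#'   samples without any call are called WT).
#' @return List with `per_gene` (tibble `gene`, `sample_id`, `status`) and
#'   `pooled` (tibble `sample_id`, `status`), status in `mutant`/`WT`.
#' @export
mutant_status <- function(snvs, cnvs, genes, samples) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  snv_hits <- dplyr::distinct(
    dplyr::filter(snvs, .data$gene %in% genes),
    .data$gene, .data$sample_id)
  cnv_hits <- dplyr::distinct(
    dplyr::filter(tibble::as_tibble(cnvs),
                  .data$gene %in% genes,
                  .data$cnv_class %in% c("homo_del", "homo_amp")),
    .data$gene, .data$sample_id)
  hits <- dplyr::distinct(dplyr::bind_rows(snv_hits, cnv_hits))
  grid <- tidyr::expand_grid(gene = genes, sample_id = samples)
  per_gene <- grid |>
    dplyr::left_join(dplyr::mutate(hits, status = "mutant"),
                     by = c("gene", "sample_id")) |>
    dplyr::mutate(status = dplyr::coalesce(.data$status, "WT"))
  pooled <- per_gene |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(status = ifelse(any(.data$status == "mutant"),
                                     "mutant", "WT"),
                     .groups = "drop")
  list(per_gene = per_gene, pooled = pooled)
}

#' Survival contrast between mutant and wild-type patients
#'
#' Two-group log-rank on pooled status and, optionally, per tested gene.
#'
#' @param status Result of [mutant_status()].
#' @param surv Survival tibble.
#' @param per_gene Also compute one comparison per gene (genes whose groups
#'   are degenerate are skipped with a message).
#' @return List with `pooled` (a `surv_comparison`) and, when `per_gene`,
#'   `by_gene` (named list of `surv_comparison`s).
#' @export
mutation_survival <- function(status, surv, per_gene = FALSE) {
  surv <- validate_survival(surv)
  pooled <- status$pooled[status$pooled$sample_id %in% surv$sample_id, ]
  counts <- table(pooled$status)
  if (length(counts) < 2 || any(counts == 0)) {
    stop("group '", setdiff(c("mutant", "WT"), names(counts)[counts > 0]),
         "' is empty", call. = FALSE)
  }
  out <- list(pooled = logrank(surv[surv$sample_id %in% pooled$sample_id, ],
                               setNames(pooled$status, pooled$sample_id)))
  if (per_gene) {
    genes <- unique(status$per_gene$gene)
    out$by_gene <- purrr::compact(setNames(lapply(genes, function(gn) {
      st <- status$per_gene[status$per_gene$gene == gn &
                              status$per_gene$sample_id %in% surv$sample_id, ]
      if (length(unique(st$status)) < 2) {
        message("skipping ", gn, ": only one status group")
        return(NULL)
      }
      logrank(surv[surv$sample_id %in% st$sample_id, ],
              setNames(st$status, st$sample_id))
    }), genes))
  }
  out
}
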