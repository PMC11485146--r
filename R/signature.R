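#' Intersect critical nodes with a curated gene list
#'
#' @param control A `control_result` from [critical_nodes()] (or a character
#'   vector of critical genes).
#' @param curated A [gene_set()] (or character vector) of curated genes.
#' @return Sorted character vector of critical curated genes (possibly empty).
#' @export
intersect_ccgs <- function(control, curated) {
  crit <- if (inherits(control, "control_result")) critical_set(control) else control
  cur <- if (inherits(curated, "gene_set")) curated$genes else curated
  sort(intersect(crit, cur))
}

#' Aggregate per-cancer critical curated genes into a pan-cancer catalog
#'
#' Takes the per-cancer-type sets of critical curated genes, unions them with
#' duplicates removed, and counts in how many cancer types each gene occurs;
#' genes occurring in two or more types are flagged multi-cancer.
#'
#' @param per_cancer Named list: cancer type -> character vector of genes.
#' @return A tibble of class `ccg_catalog` with columns `gene`, `occurrence`,
#'   `multi_cancer`, `cancer_types` (comma-separated).
#' @export
aggregate_pan_cancer <- function(per_cancer) {
  if (length(per_cancer) == 0) stop("no cancer types supplied", call. = FALSE)
  if (is.null(names(per_cancer)) || any(!nzchar(names(per_cancer)))) {
    stop("per_cancer must be a named list", call. = FALSE)
  }
  long <- tibble::tibble(
    cancer_type = rep(names(per_cancer), lengths(per_cancer)),
    gene = unlist(per_cancer, use.names = FALSE)
  )
  long <- dplyr::distinct(long)
  out <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(occurrence = dplyr::n(),
                     cancer_types = paste(sort(.data$cancer_type),
                                          collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(multi_cancer = .data$occurrence >= 2) |>
    dplyr::arrange(dplyr::desc(.data$occurrence), .data$gene)
  class(out) <- c("ccg_catalog", class(out))
  out
}

#' Univariate Cox proportional-hazards screen for one covariate
#'
#' Fits `Surv(time, event) ~ x` and reports the hazard ratio and Wald
#' p-value. A constant covariate carries no information and returns
#' `hr = 1, p = 1` by convention.
#'
#' @param surv Survival tibble (see [read_survival()]).
#' @param x Named numeric vector of covariate values; names are sample ids
#'   and must cover `surv$sample_id`.
#' @return A one-row tibble: `beta`, `hr`, `se`, `p_value`, `n`, `n_events`.
#' @export
univariate_cox <- function(surv, x) {
  surv <- validate_survival(surv)
  if (is.null(names(x))) stop("covariate must be named by sample id", call. = FALSE)
  missing <- setdiff(surv$sample_id, names(x))
  if (length(missing) > 0) {
    stop("covariate missing for samples: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  xv <- x[surv$sample_id]
  if (sum(surv$event) == 0) stop("no events observed", call. = FALSE)
  if (sd(xv) == 0) {
    return(tibble::tibble(beta = 0, hr = 1, se = NA_real_, p_value = 1,
                          n = nrow(surv), n_events = sum(surv$event)))
  }
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ xv)
  s <- summary(fit)
  tibble::tibble(beta = unname(coef(fit)),
                 hr = unname(exp(coef(fit))),
                 se = unname(s$coefficients[, "se(coef)"]),
                 p_value = unname(s$coefficients[, "Pr(>|z|)"]),
                 n = nrow(surv), n_events = sum(surv$event))
}

#' Univariate Cox screen over a gene panel
#'
#' Runs [univariate_cox()] for each gene's log2 expression across the cohort
#' and flags genes with Wald `p <= alpha` as prognostic.
#'
#' @param x An [expression_matrix()] on the log2 scale (tumour samples with
#'   survival data are used).
#' @param surv Survival tibble.
#' @param genes Genes to screen (default: all rows of `x`).
#' @param alpha Significance threshold (default 0.05).
#' @return A tibble with one row per gene: `gene`, `beta`, `hr`, `p_value`,
#'   `selected`.
#' @export
cox_screen <- function(x, surv, genes = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "expr_mat"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- genes %||% rownames(x$values)
  genes <- intersect(genes, rownames(x$values))
  surv <- validate_survival(surv)
  surv <- surv[surv$sample_id %in% colnames(x$values), ]
  purrr::map_dfr(genes, function(g) {
    res <- univariate_cox(surv, x$values[g, ])
    tibble::tibble(gene = g, beta = res$beta, hr = res$hr,
                   p_value = res$p_value)
  }) |>
    dplyr::mutate(selected = .data$p_value <= alpha)
}

#' Majority-vote regulation direction for a catalog gene
#'
#' Among the cancer types where a gene is a critical curated gene, counts
#' significant `up` versus `down` DE statuses (non-significant statuses do
#' not vote); a strict majority decides, otherwise the gene is
#' `unclassified` and dropped from directional signatures.
#'
#' @param gene Gene symbol.
#' @param de_by_cancer Named list: cancer type -> [de_test()] tibble.
#' @param membership Named list: cancer type -> character vector of CCGs.
#' @return One of `"up"`, `"down"`, `"unclassified"`.
#' @export
assign_direction <- function(gene, de_by_cancer, membership) {
  types <- names(membership)[vapply(membership, function(g) gene %in% g,
                                    logical(1))]
  if (length(types) == 0) stop(gene, " is not a CCG anywhere", call. = FALSE)
  statuses <- vapply(types, function(ct) {
    de <- de_by_cancer[[ct]]
    st <- de$status[de$gene_id == gene]
    if (length(st) == 0) "ns" else st
  }, character(1))
  n_up <- sum(statuses == "up"); n_down <- sum(statuses == "down")
  if (n_up > n_down) "up" else if (n_down > n_up) "down" else "unclassified"
}

#' Directions for every gene of a catalog
#'
#' @param catalog A `ccg_catalog` from [aggregate_pan_cancer()].
#' @param de_by_cancer Named list of [de_test()] tibbles.
#' @param membership Named list: cancer type -> CCG vector.
#' @return The catalog tibble with a `direction` column added.
#' @export
catalog_directions <- function(catalog, de_by_cancer, membership) {
  catalog$direction <- vapply(catalog$gene, assign_direction,
                              character(1),
                              de_by_cancer = de_by_cancer,
                              membership = membership)
  catalog
}

# ---- patient stratification -------------------------------------------------

#' Spectral stratification of patients on a gene signature
#'
#' Computes squared Euclidean distances between all pairs of patients over
#' the signature genes' expression, converts them to a locally scaled
#' Gaussian affinity (the scale for a pair blends each point's mean distance
#' to its `K` nearest neighbours with the pair distance, damped by `mu`),
#' and partitions the normalized-Laplacian spectral embedding into `k`
#' groups with seeded k-means.
#'
#' @param x An [expression_matrix()] (log2 scale) restricted or restrictable
#'   to the signature genes.
#' @param genes Signature genes (default: all rows).
#' @param k Number of groups (default 2).
#' @param K Neighbourhood size of the local scale (default 20).
#' @param mu Kernel width multiplier (default 0.5).
#' @param seed Integer seed for the k-means initialization.
#' @return A tibble `sample_id`, `cluster` (integer in `1:k`).
#' @export
spectral_stratify <- function(x, genes = NULL, k = 2, K = 20, mu = 0.5,
                              seed = 1) {
  stopifnot(inherits(x, "expr_mat"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- genes %||% rownames(x$values)
  v <- t(x$values[genes, , drop = FALSE])  # samples x genes
  n <- nrow(v)
  if (k > n) stop("more clusters than samples", call. = FALSE)
  d2 <- as.matrix(stats::dist(v))^2
  w <- local_scale_affinity(d2, K = K, mu = mu)
  lab <- spectral_partition(w, k = k, seed = seed)
  tibble::tibble(sample_id = colnames(x$values), cluster = lab)
}

# Locally scaled Gaussian affinity from a squared-distance matrix.
local_scale_affinity <- function(d2, K = 20, mu = 0.5) {
  n <- nrow(d2)
  K <- min(K, n - 1)
  d <- sqrt(d2)
  near_mean <- apply(d, 1, function(row) {
    mean(sort(row[-which.min(row)])[seq_len(K)])
  })
  # pairwise scale: average of the two local scales and the pair distance
  sig <- (outer(near_mean, near_mean, "+") + d) / 3
  sig <- pmax(sig, .Machine$double.eps)
  w <- exp(-d2 / (2 * (mu * sig)^2))
  (w + t(w)) / 2
}

# Normalized-Laplacian spectral embedding + seeded kmeans.
spectral_partition <- function(w, k, seed) {
  deg <- rowSums(w)
  deg[deg == 0] <- .Machine$double.eps
  dinv <- 1 / sqrt(deg)
  l <- t(w * dinv) * dinv          # D^{-1/2} W D^{-1/2}
  eig <- eigen((l + t(l)) / 2, symmetric = TRUE)
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  u <- u / pmax(norms, .Machine$double.eps)
  km <- withr::with_seed(seed, kmeans(u, centers = k, nstart = 20,
                                      iter.max = 100))
  # relabel deterministically: cluster 1 = cluster containing first sample
  relabel <- match(km$cluster, unique(km$cluster))
  as.integer(relabel)
}

#' Median-dichotomize an expression vector
#'
#' Values strictly above the cohort median are `high`; values at or below
#' the median (ties included) are `low`.
#'
#' @param x Named numeric vector (names are sample ids), length >= 2.
#' @return Named character vector of `"high"` / `"low"`.
#' @export
median_dichotomize <- function(x) {
  if (length(x) < 2) stop("need >= 2 samples", call. = FALSE)
  m <- median(x)
  setNames(ifelse(x > m, "high", "low"), names(x))
}

#' Dichotomize several genes across a cohort
#'
#' @param x An [expression_matrix()].
#' @param genes Genes to dichotomize.
#' @return A tibble `sample_id`, `gene`, `level` (`high`/`low`).
#' @export
dichotomize_genes <- function(x, genes) {
  stopifnot(inherits(x, "expr_mat"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  purrr::map_dfr(genes, function(g) {
    lv <- median_dichotomize(x$values[g, ])
    tibble::tibble(sample_id = names(lv), gene = g, level = unname(lv))
  })
}

#' Assign combined-signature subtypes from high/low calls
#'
#' Implements the combined subtype rule: subtype 2 is the good-prognosis
#' pattern (high on every gene of `high_genes`, low on every gene of
#' `low_genes`), subtype 1 is the exact mirror (low on all `high_genes`,
#' high on all `low_genes`), and subtype 3 is every other pattern.
#'
#' @param highlow Tibble from [dichotomize_genes()] covering all rule genes.
#' @param high_genes Genes required high for subtype 2 (e.g. MAP1LC3A, SNCA,
#'   MAPT in the pan-cancer 8-gene rule).
#' @param low_genes Genes required low for subtype 2 (e.g. CDK1, AP1S1,
#'   CASP3, TMPRSS6, GSK3B). Must be disjoint from `high_genes`.
#' @return A tibble `sample_id`, `subtype` (integer 1/2/3).
#' @export
assign_signature_subtype <- function(highlow, high_genes, low_genes) {
  if (length(intersect(high_genes, low_genes)) > 0) {
    stop("high and low gene sets overlap", call. = FALSE)
  }
  rule <- c(high_genes, low_genes)
  missing <- setdiff(rule, unique(highlow$gene))
  if (length(missing) > 0) {
    stop("no dichotomized calls for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wide <- highlow |>
    dplyr::filter(.data$gene %in% rule) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "level")
  mat <- as.matrix(wide[, rule])
  want2 <- c(rep("high", length(high_genes)), rep("low", length(low_genes)))
  want1 <- c(rep("low", length(high_genes)), rep("high", length(low_genes)))
  is2 <- rowSums(mat == matrix(want2, nrow(mat), length(rule), byrow = TRUE)) ==
    length(rule)
  is1 <- rowSums(mat == matrix(want1, nrow(mat), length(rule), byrow = TRUE)) ==
    length(rule)
  tibble::tibble(sample_id = wide$sample_id,
                 subtype = ifelse(is2, 2L, ifelse(is1, 1L, 3L)))
}

# ---- survival comparison ----------------------------------------------------

#' Kaplan-Meier product-limit curves per group
#'
#' @param surv Survival tibble.
#' @param groups Named vector (names = sample ids) or tibble
#'   (`sample_id` + one grouping column) of group labels.
#' @return A tibble `group`, `time`, `n_risk`, `n_event`, `survival`; curves
#'   start at 1 and are non-increasing.
#' @export
km_curves <- function(surv, groups) {
  surv <- validate_survival(surv)
  g <- normalize_groups(groups, surv$sample_id)
  purrr::map_dfr(sort(unique(g)), function(lev) {
    sub <- surv[g[surv$sample_id] == lev, ]
    times <- sort(unique(sub$time[sub$event == 1]))
    n_risk <- vapply(times, function(t) sum(sub$time >= t), numeric(1))
    n_event <- vapply(times, function(t) sum(sub$time == t & sub$event == 1),
                      numeric(1))
    s <- cumprod(1 - n_event / n_risk)
    tibble::tibble(group = lev, time = c(0, times),
                   n_risk = c(nrow(sub), n_risk),
                   n_event = c(0, n_event), survival = c(1, s))
  })
}

#' K-group log-rank test with Kaplan-Meier curves
#'
#' Computes the classical log-rank chi-square from the observed-minus-
#' expected event counts across the pooled event times, with the
#' hypergeometric covariance, on `k - 1` degrees of freedom. Empty groups
#' are dropped with a warning.
#'
#' @param surv Survival tibble.
#' @param groups Group labels (named vector or tibble `sample_id` + label
#'   column, e.g. the output of [assign_signature_subtype()] or
#'   [spectral_stratify()]).
#' @return An object of class `surv_comparison`: list with `chisq`, `df`,
#'   `p_value`, `n`, `groups` (per-group n and events) and `km` (tibble from
#'   [km_curves()]). Has [tidy()][generics::tidy] / `glance()`-style
#'   accessors via `tidy.surv_comparison()` and `glance.surv_comparison()`.
#' @export
logrank <- function(surv, groups) {
  surv <- validate_survival(surv)
  g <- normalize_groups(groups, surv$sample_id)
  g <- g[surv$sample_id]
  counts <- table(g)
  if (any(counts == 0)) {
    warning("dropping empty groups: ",
            paste(names(counts)[counts == 0], collapse = ", "))
  }
  levels <- names(counts)[counts > 0]
  if (length(levels) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  keep <- g %in% levels
  time <- surv$time[keep]; event <- surv$event[keep]; g <- factor(g[keep], levels)
  if (sum(event) == 0) stop("no events observed", call. = FALSE)
  k <- length(levels)
  event_times <- sort(unique(time[event == 1]))
  o <- e <- numeric(k)
  v <- matrix(0, k, k)
  for (t in event_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(time == t & event == 1)
    n_gj <- vapply(levels, function(l) sum(at_risk & g == l), numeric(1))
    d_gj <- vapply(levels, function(l) sum(time == t & event == 1 & g == l),
                   numeric(1))
    o <- o + d_gj
    e <- e + d_j * n_gj / n_j
    if (n_j > 1) {
      frac <- d_j * (n_j - d_j) / (n_j - 1)
      vj <- -outer(n_gj, n_gj) / n_j^2
      diag(vj) <- n_gj * (n_j - n_gj) / n_j^2
      v <- v + frac * vj
    }
  }
  idx <- seq_len(k - 1)
  diffv <- (o - e)[idx]
  vv <- v[idx, idx, drop = FALSE]
  chisq <- if (all(abs(diffv) < 1e-12)) 0 else
    as.numeric(t(diffv) %*% solve(vv, diffv))
  p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  structure(list(
    chisq = chisq, df = k - 1, p_value = p, n = length(time),
    groups = tibble::tibble(group = levels,
                            n = as.integer(table(g)[levels]),
                            events = vapply(levels, function(l)
                              sum(event[g == l]), numeric(1))),
    km = km_curves(surv[keep, ], setNames(as.character(g), surv$sample_id[keep]))
  ), class = "surv_comparison")
}

normalize_groups <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    if (!"sample_id" %in% names(groups)) {
      stop("group table needs a sample_id column", call. = FALSE)
    }
    label_col <- setdiff(names(groups), "sample_id")[1]
    g <- setNames(as.character(groups[[label_col]]), groups$sample_id)
  } else {
    if (is.null(names(groups))) {
      if (length(groups) != length(sample_ids)) {
        stop("unnamed group vector must match sample count", call. = FALSE)
      }
      g <- setNames(as.character(groups), sample_ids)
    } else {
      g <- setNames(as.character(groups), names(groups))
    }
  }
  missing <- setdiff(sample_ids, names(g))
  if (length(missing) > 0) {
    stop("group label missing for samples: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  g
}

#' @exportS3Method base::print
print.surv_comparison <- function(x, ...) {
  cat(sprintf("<surv_comparison> %d groups, n = %d, chisq = %.3f (df %d), p = %.3g\n",
              nrow(x$groups), x$n, x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Tidy a survival comparison
#' @param x A `surv_comparison`.
#' @param ... Unused.
#' @return Per-group tibble with n, events and KM curve rows nested out;
#'   use `x$km` for the full step functions.
#' @export
tidy.surv_comparison <- function(x, ...) x$groups

#' One-row summary of a survival comparison
#' @param x A `surv_comparison`.
#' @param ... Unused.
#' @return Tibble with `chisq`, `df`, `p_value`, `n`.
#' @export
glance.surv_comparison <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p_value = x$p_value, n = x$n)
}

#' Kaplan-Meier plot of a survival comparison
#' @param x A `surv_comparison` from [logrank()].
#' @param ... Unused.
#' @return A ggplot object with one step curve per group.
#' @export
plot_km <- function(x, ...) {
  ggplot2::ggplot(x$km, ggplot2::aes(x = .data$time, y = .data$survival,
                                     colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "group",
                  subtitle = sprintf("log-rank p = %.3g", x$p_value)) +
    ggplot2::theme_minimal()
}
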