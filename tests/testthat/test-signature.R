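test_that("CCG intersection and pan-cancer aggregation behave as set ops", {
  ctrl <- tibble::tibble(node = c("A", "B", "C"),
                         class = c("critical", "critical", "critical"),
                         mdns_after = c(2L, 2L, 2L))
  class(ctrl) <- c("control_result", class(ctrl))
  attr(ctrl, "mdns_size") <- 1L
  expect_setequal(intersect_ccgs(ctrl, gene_set("cu", c("B", "D"))), "B")
  expect_length(intersect_ccgs(c("A"), c("X")), 0)
  expect_setequal(intersect_ccgs(c("A", "B", "C"), c("A", "B")), c("A", "B"))

  cat23 <- aggregate_pan_cancer(list(ACC = c("g1", "g2"), BRCA = c("g2", "g3")))
  expect_setequal(cat23$gene, c("g1", "g2", "g3"))
  expect_equal(cat23$occurrence[cat23$gene == "g2"], 2)
  expect_true(cat23$multi_cancer[cat23$gene == "g2"])
  expect_false(any(cat23$multi_cancer[cat23$gene != "g2"]))

  single <- aggregate_pan_cancer(list(ACC = c("g1", "g2")))
  expect_false(any(single$multi_cancer))
})

test_that("a 23-cohort fixture aggregates to 57 genes of which 40 multi-cancer", {
  # constructed so the union is 57 unique genes and exactly 40 recur
  genes <- sprintf("CCG%02d", 1:57)
  multi <- genes[1:40]; once <- genes[41:57]
  per_cancer <- lapply(1:23, function(i) character(0))
  names(per_cancer) <- sprintf("CT%02d", 1:23)
  for (j in seq_along(multi)) {
    hosts <- ((j + 0:1) %% 23) + 1          # each multi gene in 2 cohorts
    for (h in hosts) per_cancer[[h]] <- c(per_cancer[[h]], multi[j])
  }
  for (j in seq_along(once)) {
    per_cancer[[(j %% 23) + 1]] <- c(per_cancer[[(j %% 23) + 1]], once[j])
  }
  cat <- aggregate_pan_cancer(per_cancer)
  expect_equal(nrow(cat), 57)
  expect_equal(sum(cat$multi_cancer), 40)
})

test_that("univariate Cox recovers a planted log-hazard and handles degenerate input", {
  withr::with_seed(31, {
    n <- 2000
    x <- rnorm(n)
    t_event <- rexp(n, rate = 0.01 * exp(0.7 * x))
    t_cens <- rexp(n, rate = 0.004)        # roughly 30% censoring
    surv <- tibble::tibble(
      sample_id = sprintf("P%04d", 1:n),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      age = NA_real_, sex = NA_character_, cancer_type = "SIM")
  })
  censoring <- 1 - mean(surv$event)
  expect_gt(censoring, 0.15); expect_lt(censoring, 0.45)
  fit <- univariate_cox(surv, setNames(x, surv$sample_id))
  expect_lt(abs(fit$beta - 0.7), 0.1)

  const <- univariate_cox(surv, setNames(rep(1, n), surv$sample_id))
  expect_equal(const$hr, 1)
  expect_equal(const$p_value, 1)

  no_events <- dplyr::mutate(surv, event = 0)
  expect_error(univariate_cox(no_events, setNames(x, surv$sample_id)),
               "no events")
})

test_that("direction votes use strict majority over significant statuses only", {
  de_for <- function(status) tibble::tibble(gene_id = "g", log2fc = 0,
                                            p_value = 0.5, adj_p = 0.5,
                                            status = status)
  membership <- list(A = "g", B = "g", C = "g")
  expect_equal(assign_direction("g", list(A = de_for("up"), B = de_for("up"),
                                          C = de_for("down")), membership),
               "up")
  expect_equal(assign_direction("g", list(A = de_for("up"),
                                          B = de_for("down")),
                                list(A = "g", B = "g")),
               "unclassified")
  expect_equal(assign_direction("g", list(A = de_for("ns"), B = de_for("ns"),
                                          C = de_for("down")), membership),
               "down")
  expect_error(assign_direction("h", list(A = de_for("up")), list(A = "g")),
               "not a CCG")
})

test_that("spectral stratification separates well-separated blobs exactly", {
  aris <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      n_half <- 50
      truth <- rep(1:2, each = n_half)
      m <- sapply(truth, function(g) rnorm(5, mean = ifelse(g == 1, 0, 10)))
      rownames(m) <- paste0("g", 1:5)
      colnames(m) <- sprintf("s%03d", 1:(2 * n_half))
    })
    cl <- spectral_stratify(log2_expr(m), k = 2, seed = seed)
    adjusted_rand(cl$cluster, truth)
  }, numeric(1))
  expect_true(all(aris == 1))
})

test_that("spectral partition is invariant to sample order and ties duplicates", {
  withr::with_seed(42, {
    m <- sapply(rep(1:2, each = 30), function(g) rnorm(4, 5 * g))
    rownames(m) <- paste0("g", 1:4)
    colnames(m) <- sprintf("s%02d", 1:60)
  })
  x <- log2_expr(m)
  cl <- spectral_stratify(x, k = 2, seed = 3)
  perm <- withr::with_seed(9, sample(60))
  cl_perm <- spectral_stratify(log2_expr(m[, perm]), k = 2, seed = 3)
  joined <- dplyr::inner_join(cl, cl_perm, by = "sample_id")
  expect_equal(adjusted_rand(joined$cluster.x, joined$cluster.y), 1)

  # exact duplicates always co-cluster
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("d%03d", 1:120)
  cld <- spectral_stratify(log2_expr(dup), k = 2, seed = 3)
  first <- cld$cluster[1:60]; second <- cld$cluster[61:120]
  expect_equal(first, second)

  expect_error(spectral_stratify(x, k = 61), "more clusters")
})

test_that("median dichotomization sends ties low", {
  expect_equal(unname(median_dichotomize(setNames(c(1, 2, 3), c("a", "b", "c")))),
               c("low", "low", "high"))
  expect_equal(unique(unname(median_dichotomize(setNames(rep(2, 4),
                                                         paste0("s", 1:4))))),
               "low")
  expect_equal(unname(median_dichotomize(setNames(c(1, 4), c("a", "b")))),
               c("low", "high"))
  expect_error(median_dichotomize(setNames(1, "a")), ">= 2")
})

test_that("the 8-gene combined rule reproduces the subtype pattern table", {
  high_genes <- c("MAP1LC3A", "SNCA", "MAPT")
  low_genes <- c("CDK1", "AP1S1", "CASP3", "TMPRSS6", "GSK3B")
  rule <- c(high_genes, low_genes)
  # all 256 high/low patterns, one synthetic patient each
  patterns <- expand.grid(rep(list(c("high", "low")), 8),
                          stringsAsFactors = FALSE)
  names(patterns) <- rule
  highlow <- tibble::tibble(
    sample_id = rep(sprintf("p%03d", seq_len(nrow(patterns))), each = 8),
    gene = rep(rule, nrow(patterns)),
    level = as.vector(t(as.matrix(patterns))))
  got <- assign_signature_subtype(highlow, high_genes, low_genes)
  want <- apply(patterns, 1, function(row) {
    if (all(row[high_genes] == "high") && all(row[low_genes] == "low")) 2L
    else if (all(row[high_genes] == "low") && all(row[low_genes] == "high")) 1L
    else 3L
  })
  expect_equal(got$subtype[match(sprintf("p%03d", seq_len(nrow(patterns))),
                                 got$sample_id)], unname(want))
  expect_equal(sum(got$subtype == 2), 1)
  expect_equal(sum(got$subtype == 1), 1)
  expect_error(assign_signature_subtype(highlow, c("CDK1"), c("CDK1")),
               "overlap")
})

test_that("log-rank matches the hand O-E computation and survdiff", {
  surv <- tibble::tibble(sample_id = paste0("p", 1:6),
                         time = 1:6, event = 1L,
                         age = NA_real_, sex = NA_character_,
                         cancer_type = "TST")
  groups <- setNames(rep(c("A", "B"), 3), surv$sample_id)
  res <- logrank(surv, groups)
  # O_A = 3, E_A = 0.5 + 0.4 + 0.5 + 1/3 + 0.5, V = 0.25 + 0.24 + 0.25 + 2/9 + 0.25
  e_a <- 0.5 + 0.4 + 0.5 + 1 / 3 + 0.5
  v_a <- 0.25 + 0.24 + 0.25 + 2 / 9 + 0.25
  expect_equal(res$chisq, (3 - e_a)^2 / v_a, tolerance = 1e-12)
  ref <- survival::survdiff(survival::Surv(time, event) ~ grp,
                            data = dplyr::mutate(surv, grp = groups[sample_id]))
  expect_equal(res$chisq, ref$chisq, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # duplicated identical groups: exchangeable, chi-square 0
  dup <- dplyr::bind_rows(surv, dplyr::mutate(surv, sample_id = paste0("q", 1:6)))
  g2 <- setNames(rep(c("A", "B"), each = 6), dup$sample_id)
  res2 <- logrank(dup, g2)
  expect_equal(res2$chisq, 0)
  expect_equal(res2$p_value, 1)
})

test_that("three-group log-rank agrees with survdiff", {
  withr::with_seed(17, {
    n <- 90
    grp <- rep(c("A", "B", "C"), each = n / 3)
    time <- rexp(n, rate = c(A = 0.01, B = 0.02, C = 0.04)[grp])
    event <- rbinom(n, 1, 0.8)
  })
  surv <- tibble::tibble(sample_id = sprintf("p%03d", 1:n), time = time,
                         event = event, age = NA_real_, sex = NA_character_,
                         cancer_type = "TST")
  res <- logrank(surv, setNames(grp, surv$sample_id))
  ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(res$chisq, ref$chisq, tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(glance(res)$p_value,
               pchisq(ref$chisq, 2, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("KM estimator matches the product-limit on a 5-point hand example", {
  surv <- tibble::tibble(sample_id = paste0("p", 1:5),
                         time = c(2, 3, 3, 5, 8),
                         event = c(1, 1, 0, 1, 0),
                         age = NA_real_, sex = NA_character_,
                         cancer_type = "TST")
  km <- km_curves(surv, setNames(rep("all", 5), surv$sample_id))
  # hand product-limit: S(2) = 4/5, S(3) = 4/5 * 3/4 = 3/5, S(5) = 3/5 * 1/2
  expect_equal(km$survival, c(1, 4 / 5, 3 / 5, 3 / 10))
  expect_equal(km$time, c(0, 2, 3, 5))
  expect_true(all(diff(km$survival) <= 0))
  ref <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  expect_equal(km$survival[-1], ref$surv[ref$n.event > 0], tolerance = 1e-12)
})

test_that("log-rank has power at HR 3 and drops empty groups", {
  hits <- vapply(1:20, function(seed) {
    surv <- withr::with_seed(seed, make_surv_groups(200, hr = 3))
    res <- logrank(surv, setNames(surv$group, surv$sample_id))
    res$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  surv <- withr::with_seed(1, make_surv_groups(10, hr = 1))
  g <- setNames(surv$group, surv$sample_id)
  expect_error(logrank(surv, setNames(rep("A", 20), surv$sample_id)),
               ">= 2 non-empty")
})
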