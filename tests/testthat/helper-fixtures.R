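# Small in-code fixtures shared across test files.

# Tiny expression cohort with two conditions, written to temp TSVs on demand.
make_expr_fixture <- function(n_genes = 3, n_samples = 4, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("s", seq_len(n_samples))))
  })
  cond <- tibble::tibble(
    sample_id = colnames(m),
    condition = rep(c("tumour", "normal"), length.out = n_samples),
    cancer_type = "TST")
  list(values = m, condition = cond)
}

write_expr_fixture <- function(fx, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr_path <- file.path(dir, "expr.tsv")
  cond_path <- file.path(dir, "cond.tsv")
  df <- tibble::as_tibble(fx$values, rownames = "gene")
  readr::write_tsv(df, expr_path)
  readr::write_tsv(fx$condition, cond_path)
  list(expr = expr_path, cond = cond_path)
}

# Exponential two-group survival cohort with a given hazard ratio.
make_surv_groups <- function(n_per_group, hr, rate0 = 0.01,
                             censor_horizon = Inf) {
  n <- 2 * n_per_group
  group <- rep(c("A", "B"), each = n_per_group)
  t_event <- rexp(n, rate = rate0 * ifelse(group == "B", hr, 1))
  if (is.finite(censor_horizon)) {
    t_cens <- runif(n, 0, censor_horizon)
  } else {
    t_cens <- rep(Inf, n)
  }
  tibble::tibble(
    sample_id = sprintf("P%03d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    age = NA_real_, sex = NA_character_, cancer_type = "TST",
    group = group)
}

# End-to-end cohort configuration shared by the simulate and acceptance
# suites: two chains plus six stars (hubs are the planted critical nodes),
# shifts of +2 on every network gene so all enter the DEG panel, and planted
# prognostic effects of -0.8 (protective trio) / +0.8 (risk five) on the
# two dedicated stars.
e2e_config <- function(seed, n_tumour = 500, n_normal = 100) {
  ids <- sim_gene_ids(400)
  dag <- dplyr::bind_rows(
    planted_dag(n_chains = 2, chain_len = 4, n_stars = 4, star_leaves = 3,
                weight = 0.9, gene_ids = ids),
    tibble::tibble(from = ids[25], to = ids[26:27], weight = 0.9),
    tibble::tibble(from = ids[28], to = ids[29:32], weight = 0.9))
  net_genes <- unique(c(dag$from, dag$to))
  good <- ids[25:27]; bad <- ids[28:32]
  sim_config(
    n_genes = 400, n_tumour = n_tumour, n_normal = n_normal,
    network = dag,
    de_genes = stats::setNames(rep(2, length(net_genes)), net_genes),
    noise_sd = 0.5,
    lambda0 = 0.001,
    beta = stats::setNames(c(rep(-0.8, 3), rep(0.8, 5)), c(good, bad)),
    censor_horizon = 3650,
    mut_background = 0.005,
    mut_genes = stats::setNames(rep(0.2, 3), ids[25:27]),
    cnv_rate = 0.005, seed = seed)
}

# log2-scale expression matrix built directly from a values matrix.
log2_expr <- function(values, condition = NULL) {
  if (is.null(condition)) {
    condition <- tibble::tibble(sample_id = colnames(values),
                                condition = "tumour", cancer_type = "TST")
  }
  expression_matrix(values, condition, scale = "log2")
}
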