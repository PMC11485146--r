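#' Configuration for a synthetic cohort
#'
#' Bundles every knob of the generator. Defaults reproduce the study
#' conditions used throughout the test-suite's differential-expression arm:
#' a planted log2 shift of 2 against residual noise of sd 0.5 with 30
#' tumour and 30 normal samples.
#'
#' @param n_genes Total genes in the universe.
#' @param n_tumour,n_normal Samples per condition.
#' @param network Planted directed network: tibble `from`, `to`, `weight`.
#'   Edges must point from lower to higher topological order (a DAG is
#'   required; see [planted_dag()]). `NULL` for no gene-gene dependence.
#' @param de_genes Named numeric vector of planted tumour log2 shifts.
#' @param noise_sd Residual sd on the log2 scale (default 0.5).
#' @param base_mean_range Range of per-gene baseline log2 means.
#' @param lambda0 Baseline exponential hazard per day.
#' @param beta Named numeric vector of per-gene log-hazard coefficients on
#'   standardized log2 expression.
#' @param censor_horizon Administrative censoring: censoring times are
#'   Uniform(0, `censor_horizon`) days.
#' @param mut_background Per (gene, sample) background probability of a
#'   planted pathogenic SNV.
#' @param mut_genes Named numeric vector: planted mutation genes with their
#'   per-sample pathogenic SNV probability.
#' @param cnv_rate Per (gene, sample) probability of a homozygous CNV event.
#' @param seed Integer master seed; per-table substreams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_tumour = 30, n_normal = 30,
                       network = NULL, de_genes = NULL, noise_sd = 0.5,
                       base_mean_range = c(3, 8),
                       lambda0 = 0.001, beta = NULL, censor_horizon = 3650,
                       mut_background = 0.01, mut_genes = NULL,
                       cnv_rate = 0.01, seed = 1) {
  if (!is.null(network)) {
    network <- tibble::as_tibble(network)
    stopifnot(all(c("from", "to", "weight") %in% names(network)))
  }
  structure(list(n_genes = n_genes, n_tumour = n_tumour, n_normal = n_normal,
                 network = network, de_genes = de_genes, noise_sd = noise_sd,
                 base_mean_range = base_mean_range, lambda0 = lambda0,
                 beta = beta, censor_horizon = censor_horizon,
                 mut_background = mut_background, mut_genes = mut_genes,
                 cnv_rate = cnv_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene identifiers of the simulated universe
#' @param n Number of genes.
#' @return Character vector `G0001 ... G<n>`.
#' @export
sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# derive a bounded substream seed from the master seed and a stream label
substream <- function(seed, stream) {
  (seed * 97L + stream * 1009L) %% 2147483647L
}

#' Planted DAG made of chain and star motifs
#'
#' Builds a directed acyclic network over the first genes of the universe
#' from repeated chain (`a -> b -> c -> ...`) and out-star
#' (`hub -> leaves`) motifs — the two motifs with known driver-node
#' structure — with a common edge weight.
#'
#' @param n_chains Number of chain motifs.
#' @param chain_len Nodes per chain (>= 2).
#' @param n_stars Number of star motifs.
#' @param star_leaves Leaves per star.
#' @param weight Edge weight of the structural equations (default 0.9,
#'   strong dependence).
#' @param gene_ids Gene universe to draw node names from (first nodes are
#'   used in order).
#' @return Tibble `from`, `to`, `weight` in topological order.
#' @export
planted_dag <- function(n_chains = 4, chain_len = 4, n_stars = 4,
                        star_leaves = 3, weight = 0.9,
                        gene_ids = sim_gene_ids(200)) {
  need <- n_chains * chain_len + n_stars * (star_leaves + 1)
  if (need > length(gene_ids)) stop("gene universe too small", call. = FALSE)
  ids <- gene_ids[seq_len(need)]
  edges <- list()
  pos <- 1
  for (i in seq_len(n_chains)) {
    nodes <- ids[pos:(pos + chain_len - 1)]
    edges[[length(edges) + 1]] <- tibble::tibble(
      from = nodes[-chain_len], to = nodes[-1], weight = weight)
    pos <- pos + chain_len
  }
  for (i in seq_len(n_stars)) {
    hub <- ids[pos]
    leaves <- ids[(pos + 1):(pos + star_leaves)]
    edges[[length(edges) + 1]] <- tibble::tibble(
      from = hub, to = leaves, weight = weight)
    pos <- pos + star_leaves + 1
  }
  dplyr::bind_rows(edges)
}

check_dag <- function(network, gene_ids) {
  if (is.null(network) || nrow(network) == 0) return(invisible(TRUE))
  stopifnot(all(network$from %in% gene_ids), all(network$to %in% gene_ids))
  g <- igraph::graph_from_data_frame(network[, c("from", "to")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) {
    stop("planted network must be a DAG", call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate a two-condition expression matrix from a planted network
#'
#' Generates log2-scale expression by one structural-equation pass over the
#' planted DAG in topological order
#' (`x_v = base_v + sum_parents w_uv x_u + N(0, noise_sd)`), adds the
#' planted differential-expression shifts to tumour samples, and returns
#' the matrix on the count scale (`2^x - 1`, floored at 0) so it enters the
#' pipeline exactly like a real cohort.
#'
#' @param cfg A [sim_config()].
#' @return List with `expr` (an [expression_matrix()], counts scale) and
#'   `truth` (list: `de_genes`, `network`, `gene_ids`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_gene_ids(cfg$n_genes)
  check_dag(cfg$network, ids)
  n <- cfg$n_tumour + cfg$n_normal
  samples <- sprintf("S%04d", seq_len(n))
  condition <- rep(c("tumour", "normal"), c(cfg$n_tumour, cfg$n_normal))
  withr::with_seed(substream(cfg$seed, 1L), {
    base <- runif(cfg$n_genes, cfg$base_mean_range[1], cfg$base_mean_range[2])
    names(base) <- ids
    x <- matrix(rnorm(cfg$n_genes * n, mean = base, sd = cfg$noise_sd),
                nrow = cfg$n_genes, ncol = n, dimnames = list(ids, samples))
    if (!is.null(cfg$network) && nrow(cfg$network) > 0) {
      g <- igraph::graph_from_data_frame(cfg$network[, c("from", "to")],
                                         directed = TRUE)
      topo <- igraph::topo_sort(g)$name
      for (v in topo) {
        parents <- cfg$network[cfg$network$to == v, ]
        if (nrow(parents) == 0) next
        contrib <- colSums(x[parents$from, , drop = FALSE] * parents$weight)
        x[v, ] <- x[v, ] + contrib
      }
    }
    if (!is.null(cfg$de_genes)) {
      shift_genes <- intersect(names(cfg$de_genes), ids)
      x[shift_genes, condition == "tumour"] <-
        x[shift_genes, condition == "tumour"] + cfg$de_genes[shift_genes]
    }
  })
  counts <- pmax(2^x - 1, 0)
  expr <- expression_matrix(
    counts,
    tibble::tibble(sample_id = samples, condition = condition,
                   cancer_type = "SIM"),
    scale = "counts")
  list(expr = expr,
       truth = list(de_genes = names(cfg$de_genes),
                    network = cfg$network, gene_ids = ids))
}

#' Simulate proportional-hazards survival linked to expression
#'
#' Event times are exponential with hazard
#' `lambda0 * exp(sum beta_g z_g)` where `z` is the per-gene standardized
#' log2 expression of tumour samples; censoring times are
#' Uniform(0, `censor_horizon`); the observed time is the minimum and the
#' event flag marks which came first.
#'
#' @param cfg A [sim_config()] (fields `lambda0`, `beta`, `censor_horizon`).
#' @param expr The [expression_matrix()] from [simulate_expression()]
#'   (counts scale accepted; it is log-transformed internally).
#' @return A survival tibble over the tumour samples.
#' @export
simulate_survival <- function(cfg, expr) {
  stopifnot(inherits(cfg, "sim_config"), inherits(expr, "expr_mat"))
  lx <- if (expr$scale == "counts") log_transform(expr) else expr
  tum <- lx$samples$sample_id[lx$samples$condition == "tumour"]
  lp <- rep(0, length(tum))
  if (!is.null(cfg$beta)) {
    for (g in names(cfg$beta)) {
      v <- lx$values[g, tum]
      z <- if (sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, length(v))
      lp <- lp + cfg$beta[[g]] * z
    }
  }
  withr::with_seed(substream(cfg$seed, 2L), {
    event_time <- rexp(length(tum), rate = cfg$lambda0 * exp(lp))
    cens_time <- runif(length(tum), 0, cfg$censor_horizon)
  })
  tibble::tibble(
    sample_id = tum,
    time = pmin(event_time, cens_time),
    event = as.integer(event_time <= cens_time),
    age = NA_real_, sex = NA_character_, cancer_type = "SIM")
}

#' Simulate MAF-like SNV and CNV tables with planted pathogenic calls
#'
#' Planted pathogenic calls pass every filter rule (deleterious class,
#' VAF > 0.1, PASS, REVEL >= 0.95); each planted call is accompanied (at
#' rate `decoy_rate`) by a decoy that violates exactly one rule — wrong
#' class, low VAF, non-PASS, or low REVEL — so the filter's four rules are
#' each exercised. Homozygous CNV events are planted at `cnv_rate`.
#'
#' @param cfg A [sim_config()] (fields `mut_background`, `mut_genes`,
#'   `cnv_rate`).
#' @param samples Sample ids to mutate (typically tumour samples).
#' @param genes Gene universe to mutate (default: the config's universe).
#' @param decoy_rate Probability of each decoy type per planted call.
#' @return List with `maf` (call tibble in [read_maf()] layout), `cnv`
#'   (tibble `gene`, `sample_id`, `cnv_class`) and `truth` (tibble of
#'   planted pathogenic (gene, sample) pairs incl. CNV hits).
#' @export
simulate_mutations <- function(cfg, samples, genes = NULL, decoy_rate = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- genes %||% sim_gene_ids(cfg$n_genes)
  prob <- setNames(rep(cfg$mut_background, length(genes)), genes)
  if (!is.null(cfg$mut_genes)) {
    prob[names(cfg$mut_genes)] <- cfg$mut_genes
  }
  withr::with_seed(substream(cfg$seed, 3L), {
    hit <- matrix(rbinom(length(genes) * length(samples), 1,
                         rep(prob, times = length(samples))) == 1,
                  nrow = length(genes), ncol = length(samples),
                  dimnames = list(genes, samples))
    idx <- which(hit, arr.ind = TRUE)
    planted <- tibble::tibble(gene = genes[idx[, 1]],
                              sample_id = samples[idx[, 2]])
    n_p <- nrow(planted)
    maf <- tibble::tibble(
      Hugo_Symbol = planted$gene,
      Tumor_Sample_Barcode = planted$sample_id,
      Variant_Classification = sample(c("Missense_Mutation",
                                        "Nonsense_Mutation"),
                                      n_p, replace = TRUE),
      t_depth = 40L + rpois(n_p, 20),
      t_alt_count = NA_integer_,
      FILTER = "PASS",
      REVEL = runif(n_p, 0.95, 1))
    maf$t_alt_count <- vapply(maf$t_depth, function(d) {
      # VAF uniform in (0.2, 0.6): comfortably above the 0.1 rule
      as.integer(ceiling(runif(1, 0.2, 0.6) * d))
    }, integer(1))
    decoys <- list()
    if (n_p > 0 && decoy_rate > 0) {
      mk_decoy <- function(base, what) {
        out <- base
        if (what == "class") out$Variant_Classification <- "Silent"
        if (what == "vaf") out$t_alt_count <- pmax(
          as.integer(floor(0.05 * out$t_depth)), 0L)
        if (what == "filter") out$FILTER <- "germline_risk"
        if (what == "revel") out$REVEL <- runif(nrow(out), 0.3, 0.6)
        out
      }
      for (what in c("class", "vaf", "filter", "revel")) {
        pick <- runif(n_p) < decoy_rate
        if (any(pick)) decoys[[what]] <- mk_decoy(maf[pick, ], what)
      }
    }
    maf <- dplyr::bind_rows(c(list(maf), decoys))
    cnv_hit <- matrix(rbinom(length(genes) * length(samples), 1,
                             cfg$cnv_rate) == 1,
                      nrow = length(genes), ncol = length(samples),
                      dimnames = list(genes, samples))
    cidx <- which(cnv_hit, arr.ind = TRUE)
    cnv <- tibble::tibble(
      gene = genes[cidx[, 1]],
      sample_id = samples[cidx[, 2]],
      cnv_class = sample(c("homo_del", "homo_amp"), nrow(cidx),
                         replace = TRUE))
  })
  truth <- dplyr::distinct(dplyr::bind_rows(
    planted, cnv[, c("gene", "sample_id")]))
  list(maf = maf, cnv = cnv, truth = truth)
}

#' Simulate a complete cohort with planted ground truth
#'
#' One call producing everything the pipeline consumes: expression (counts),
#' condition labels, survival, an interaction database (the planted edges
#' plus decoy pairs between independent genes), a curated gene set
#' (network genes plus extras), mutation tables, and the ground truth —
#' including the critical nodes of the planted network computed by the
#' control module on the true edge set under the antiparallel convention.
#'
#' @param cfg A [sim_config()] with a non-null `network`.
#' @param n_db_decoys Decoy interaction pairs drawn between genes outside
#'   the planted network.
#' @param curated_extra Curated genes beyond the network genes.
#' @return List: `expr`, `surv`, `db`, `curated`, `maf`, `cnv`, `truth`.
#' @export
simulate_cohort <- function(cfg, n_db_decoys = 50, curated_extra = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$network)) stop("cohort simulation needs a planted network",
                                 call. = FALSE)
  sim <- simulate_expression(cfg)
  expr <- sim$expr
  surv <- simulate_survival(cfg, expr)
  ids <- sim$truth$gene_ids
  net_genes <- sort(unique(c(cfg$network$from, cfg$network$to)))
  free <- setdiff(ids, net_genes)
  db_pairs <- tibble::tibble(gene_a = cfg$network$from,
                             gene_b = cfg$network$to)
  withr::with_seed(substream(cfg$seed, 4L), {
    if (n_db_decoys > 0 && length(free) >= 2) {
      a <- sample(free, n_db_decoys, replace = TRUE)
      b <- sample(free, n_db_decoys, replace = TRUE)
      keep <- a != b
      db_pairs <- dplyr::bind_rows(db_pairs,
                                   tibble::tibble(gene_a = a[keep],
                                                  gene_b = b[keep]))
    }
    curated <- gene_set("curated",
                        c(net_genes,
                          sample(free, min(curated_extra, length(free)))))
  })
  db <- interaction_db(db_pairs)
  tum <- expr$samples$sample_id[expr$samples$condition == "tumour"]
  muts <- simulate_mutations(cfg, samples = tum)
  true_net <- gene_network(
    dplyr::bind_rows(
      tibble::tibble(from = cfg$network$from, to = cfg$network$to),
      tibble::tibble(from = cfg$network$to, to = cfg$network$from)),
    convention = "antiparallel_pairs")
  true_critical <- critical_set(critical_nodes(true_net))
  list(expr = expr, surv = surv, db = db, curated = curated,
       maf = muts$maf, cnv = muts$cnv,
       truth = list(de_genes = sim$truth$de_genes,
                    network = cfg$network,
                    critical = true_critical,
                    prognostic = names(cfg$beta %||% numeric(0)),
                    mutated = muts$truth))
}
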