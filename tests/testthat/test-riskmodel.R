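# Shared simulated training cohort: 10 genes, 6 with real effects.
make_risk_cohort <- function(n = 500, seed = 1,
                             betas = c(0.5, -0.5, 0.75, -0.75, 1, -1,
                                       0, 0, 0, 0)) {
  p <- length(betas)
  withr::with_seed(seed, {
    m <- matrix(rnorm(p * n, 6, 1), p, n,
                dimnames = list(sprintf("g%02d", seq_len(p)),
                                sprintf("s%04d", seq_len(n))))
    z <- t(scale(t(m)))
    lp <- as.numeric(crossprod(z, betas))
    t_event <- rexp(n, rate = 0.002 * exp(lp))
    t_cens <- runif(n, 0, 2500)
  })
  surv <- tibble::tibble(
    sample_id = colnames(m),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    age = NA_real_, sex = NA_character_, cancer_type = "SIM")
  list(x = log2_expr(m), surv = surv, betas = setNames(betas, rownames(m)))
}

test_that("the univariate pre-filter keeps real effects and rejects noise", {
  passes <- vapply(1:10, function(seed) {
    ch <- make_risk_cohort(n = 400, seed = seed,
                           betas = c(rep(0.6, 10), rep(0, 3)))
    kept <- cox_prefilter(ch$x, ch$surv)$genes
    sum(kept %in% names(ch$betas)[ch$betas != 0])
  }, numeric(1))
  expect_true(all(passes >= 9))                  # ~10 planted effects recovered

  # type-I: pure-noise candidates pass at roughly the nominal rate
  rates <- vapply(1:20, function(seed) {
    ch <- make_risk_cohort(n = 400, seed = 100 + seed, betas = rep(0, 10))
    mean(cox_screen(ch$x, ch$surv)$selected)
  }, numeric(1))
  expect_lt(mean(rates), 0.15)
})

test_that("LASSO-Cox CV recovers the planted support", {
  results <- lapply(1:10, function(seed) {
    ch <- make_risk_cohort(n = 500, seed = seed)
    model <- lasso_cox_cv(ch$x, ch$surv, n_folds = 10, seed = seed)
    planted <- names(ch$betas)[ch$betas != 0]
    list(recall = sum(model$genes %in% planted),
         false = sum(!model$genes %in% planted))
  })
  recalls <- vapply(results, `[[`, numeric(1), "recall")
  falses <- vapply(results, `[[`, numeric(1), "false")
  expect_true(all(recalls >= 5))
  expect_lte(mean(falses), 1)
})

test_that("selected lambda and deviance curve are reproducible bit-exactly", {
  ch <- make_risk_cohort(n = 300, seed = 4)
  m1 <- lasso_cox_cv(ch$x, ch$surv, seed = 11)
  m2 <- lasso_cox_cv(ch$x, ch$surv, seed = 11)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$cv, m2$cv)
  expect_identical(m1$coefficients, m2$coefficients)
})

test_that("coefficient magnitudes vanish at the top of the lambda grid", {
  ch <- make_risk_cohort(n = 300, seed = 9)
  surv <- ch$surv
  xm <- t(ch$x$values[, surv$sample_id])
  xs <- scale(xm)
  y <- survival::Surv(surv$time, surv$event)
  fit <- glmnet::glmnet(xs, y, family = "cox", alpha = 1, nlambda = 100,
                        lambda.min.ratio = 0.001, standardize = FALSE)
  expect_equal(sum(abs(coef(fit, s = max(fit$lambda)))), 0)
  expect_gt(sum(abs(coef(fit, s = min(fit$lambda)))), 0)
})

test_that("a nearly unpenalized fit agrees with unpenalized coxph", {
  ch <- make_risk_cohort(n = 400, seed = 2, betas = c(0.8, 0))
  surv <- ch$surv
  xs <- scale(t(ch$x$values[, surv$sample_id]))
  y <- survival::Surv(surv$time, surv$event)
  fit <- glmnet::glmnet(xs, y, family = "cox", alpha = 1,
                        lambda = c(0.5, 1e-7), standardize = FALSE,
                        thresh = 1e-14)
  ref <- survival::coxph(y ~ xs)
  expect_equal(as.numeric(coef(fit, s = 1e-7)), unname(coef(ref)),
               tolerance = 1e-3)
})

test_that("risk scores are the linear predictor and demand model genes", {
  model <- structure(list(genes = c("gA", "gB"), coefficients = c(0.5, -0.2),
                          lambda = 0.1, log_lambda = log(0.1), cv = NULL,
                          center = setNames(c(0, 0), c("gA", "gB")),
                          scale = setNames(c(1, 1), c("gA", "gB"))),
                     class = "risk_model")
  expect_equal(risk_score(model, setNames(c(2, 1), c("gA", "gB"))), 0.8)
  expect_equal(risk_score(model, setNames(c(0, 0), c("gA", "gB"))), 0)
  s1 <- risk_score(model, setNames(c(2, 1), c("gA", "gB")))
  s2 <- risk_score(model, setNames(c(4, 1), c("gA", "gB")))
  expect_gt(s2, s1)
  expect_error(risk_score(model, setNames(1, "gA")), "gB")
})

test_that("models serialize to JSON and score identically after reload", {
  ch <- make_risk_cohort(n = 300, seed = 6)
  model <- lasso_cox_cv(ch$x, ch$surv, seed = 5)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_risk_model(model, path)
  back <- read_risk_model(path)
  expect_equal(back$genes, model$genes)
  expect_equal(risk_score(back, ch$x), risk_score(model, ch$x))
  expect_s3_class(tidy(model), "tbl_df")
  expect_equal(nrow(glance(model)), 1)
})

test_that("time-dependent AUC is 1 for a perfect marker and 0 for its reverse", {
  withr::with_seed(13, {
    n <- 100
    time <- sort(rexp(n, 0.01))
  })
  surv <- tibble::tibble(sample_id = sprintf("p%03d", 1:n), time = time,
                         event = 1L, age = NA_real_, sex = NA_character_,
                         cancer_type = "SIM")
  perfect <- setNames(-time, surv$sample_id)   # higher score = earlier death
  horizons <- unname(quantile(time, c(0.25, 0.5, 0.75)))
  auc <- time_dependent_auc(perfect, surv, horizons)
  expect_equal(auc$auc, rep(1, 3))
  auc_rev <- time_dependent_auc(-perfect, surv, horizons)
  expect_equal(auc_rev$auc, rep(0, 3))
})

test_that("a null marker scores AUC 0.5 on average", {
  aucs <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 1000
      time <- rexp(n, 0.005)
      cens <- runif(n, 0, 400)
      score <- rnorm(n)
    })
    surv <- tibble::tibble(sample_id = sprintf("p%04d", 1:n),
                           time = pmin(time, cens),
                           event = as.integer(time <= cens),
                           age = NA_real_, sex = NA_character_,
                           cancer_type = "SIM")
    time_dependent_auc(setNames(score, surv$sample_id), surv,
                       median(surv$time))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("horizons beyond follow-up are reported as missing with a warning", {
  surv <- tibble::tibble(sample_id = paste0("p", 1:5), time = c(1, 2, 3, 4, 5),
                         event = c(1, 1, 0, 1, 0), age = NA_real_,
                         sex = NA_character_, cancer_type = "SIM")
  scores <- setNames(5:1, surv$sample_id)
  expect_warning(res <- time_dependent_auc(scores, surv, c(2.5, 10)),
                 "beyond the last follow-up")
  expect_false(is.na(res$auc[1]))
  expect_true(is.na(res$auc[2]))
})
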