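test_that("log-likelihood matches closed forms and a per-row oracle", {
  fx <- toy_fit_fixture()
  ds <- fx$dataset
  spec <- fx$spec
  n <- nrow(ds$observations) / 2
  expect_equal(log_likelihood(ds, spec, rep(0, 8)), n * log(0.5),
               tolerance = 1e-12)
  # independent oracle: per-set softmax probabilities multiplied up
  beta <- c(0.4, -0.1, 0.2, 0, -0.3, 0.1, 0.5, 0.05)
  obs <- ds$observations
  key <- paste(obs$respondent_id, obs$set_id)
  ll <- 0
  for (k in unique(key)) {
    rows <- obs[key == k, ]
    rows <- rows[order(rows$alt), ]
    u <- sapply(1:2, function(j) {
      prof <- setNames(unlist(rows[j, schema_ids_t(fx$schema)]),
                       schema_ids_t(fx$schema))
      sum(effects_code(fx$schema, prof) * beta)
    })
    pj <- exp(u) / sum(exp(u))
    ll <- ll + log(pj[rows$chosen == 1L])
  }
  expect_equal(log_likelihood(ds, spec, beta), ll, tolerance = 1e-10)
  expect_error(log_likelihood(ds, spec, rep(0, 5)), "length")
})

test_that("log-likelihood saturates toward zero for a dominant utility", {
  sch <- toy_schema(2)
  obs <- data.frame(respondent_id = 1L, set_id = 1L, alt = 1:2,
                    a1 = c("positive", "negative"),
                    a2 = c("no_change", "no_change"),
                    chosen = c(1L, 0L), stringsAsFactors = FALSE)
  ds <- structure(list(respondents = data.frame(id = 1L),
                       observations = obs, schema = sch),
                  class = "choice_dataset")
  spec <- model_spec(sch)
  lls <- sapply(c(1, 5, 20), function(s)
    log_likelihood(ds, spec, c(s, 0, 0, 0)))
  expect_true(all(diff(lls) > 0))
  expect_gt(lls[3], -1e-8)
  expect_lt(lls[3], 0)
})

test_that("the MLE is deterministic and matches conditional logistic fits", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  fx <- toy_fit_fixture()
  fit1 <- fit_mnl(fx$dataset, fx$spec)
  fit2 <- fit_mnl(fx$dataset, fx$spec)
  expect_identical(fit1$coefficients, fit2$coefficients)
  expect_true(fit1$converged)
  expect_lte(fit1$gradient_norm, 1e-6)
  obs <- fx$dataset$observations
  X <- ppdce:::effects_code_matrix(fx$schema, obs[, schema_ids_t(fx$schema)])
  df <- data.frame(y = obs$chosen, X,
                   strat = paste(obs$respondent_id, obs$set_id))
  env <- new.env(parent = globalenv())
  env$strata <- survival::strata
  fml <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = "+"),
                                 "+ strata(strat)"), env = env)
  cf <- coef(survival::clogit(fml, data = df))
  expect_equal(unname(fit1$coefficients), unname(cf), tolerance = 1e-6)
})

test_that("the fitted optimum improves on the null and on perturbations", {
  fx <- toy_fit_fixture()
  fit <- fit_mnl(fx$dataset, fx$spec)
  ll0 <- log_likelihood(fx$dataset, fx$spec, rep(0, 8))
  expect_gt(fit$log_likelihood, ll0)
  set.seed(1)
  for (i in 1:5) {
    pert <- fit$coefficients + rnorm(8, 0, 0.05)
    expect_gte(fit$log_likelihood, log_likelihood(fx$dataset, fx$spec, pert))
  }
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("estimates are invariant to relabeling the alternative order", {
  fx <- toy_fit_fixture()
  ds2 <- fx$dataset
  obs <- ds2$observations
  key <- paste(obs$respondent_id, obs$set_id)
  flip <- key %in% unique(key)[c(TRUE, FALSE)]
  obs$alt[flip] <- 3L - obs$alt[flip]
  ds2$observations <- obs
  fit1 <- fit_mnl(fx$dataset, fx$spec)
  fit2 <- fit_mnl(ds2, fx$spec)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit1$log_likelihood, fit2$log_likelihood, tolerance = 1e-10)
})

test_that("never-varying attributes raise an identifiability error", {
  fx <- toy_fit_fixture()
  ds2 <- fx$dataset
  ds2$observations$a2 <- "no_change"
  expect_error(fit_mnl(ds2, fx$spec), "a2")
})

test_that("interaction models recover subgroup offsets", {
  fx <- toy_fit_fixture()
  truth <- truth_spec(fx$base, interactions = list(
    list(covariate = "physician", attribute = "a1",
         offsets = c(0.3, 0, -0.3))), completion = 1)
  pop <- generate_population(800, seed = 21, n_blocks = 1)
  ds <- simulate_choices(fx$design, pop, truth, seed = 22)
  spec <- spec_from_truth(fx$schema, truth)
  fit <- fit_mnl(ds, spec)
  expect_length(fit$coefficients, 10L)
  tb <- true_beta_centered(fit, truth, fx$schema)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - tb) < 4 * se))
  expect_error(fit_mnl(ds, model_spec(fx$schema,
                                      interactions = list(c("nope", "a1")))),
               "nope")
})

test_that("LR statistics are zero for a null comparison and valid generally", {
  fx <- toy_fit_fixture()
  fit <- fit_mnl(fx$dataset, fx$spec)
  lrt <- lr_table(fx$dataset, fx$spec, fit)
  expect_true(all(lrt$statistic >= 0))
  expect_true(all(lrt$df == 2L))
  expect_true(all(lrt$p_value > 0 & lrt$p_value <= 1))
  expect_equal(lrt$log_p, log(lrt$p_value), tolerance = 1e-8)
  # duplicating the full model as "reduced" gives statistic 0, p = 1
  expect_equal(max(0, 2 * (fit$log_likelihood - fit$log_likelihood)), 0)
  expect_equal(pchisq(0, 2, lower.tail = FALSE), 1)
  expect_error(lr_test_attribute(fx$dataset, fx$spec, fit, "zz"),
               "unknown attribute")
})

test_that("estimation error shrinks as the sample grows", {
  fx <- toy_fit_fixture()
  truth <- truth_spec(fx$base, completion = 0.9)
  mae <- sapply(c(100, 250, 547, 1500), function(n) {
    reps <- sapply(1:2, function(r) {
      pop <- generate_population(n, seed = n + r, n_blocks = 1)
      ds <- simulate_choices(fx$design, pop, truth, seed = 10 * n + r)
      fit <- fit_mnl(ds, fx$spec)
      mean(abs(fit$coefficients - fx$base))
    })
    mean(reps)
  })
  expect_lt(mae[4], mae[1])
  # monotone within simulation error: no step may grow by more than 20%
  expect_true(all(diff(mae) < 0.2 * mae[-4]))
})
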