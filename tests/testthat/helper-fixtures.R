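# Shared fixtures. Study-scale objects are expensive (design optimization),
# so they are built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_schema <- function(K, ref_level = "negative") {
  build_schema(list(
    attributes = lapply(seq_len(K), function(i)
      list(id = paste0("a", i), name = paste("Attribute", i), rank = i)),
    reference = list(attribute = "a1", level = ref_level)))
}

study_schema_t <- function() cached("schema", build_schema())

study_prior_t <- function() {
  cached("prior", build_ordered_prior(study_schema_t(), draws = 256L,
                                      seed = 11L))
}

# the full-size optimized design used by design-structure and simulation
# tests (54 sets, 3 blocks, <= 5 varying attributes, 4 restarts, 256 draws)
study_design_t <- function() {
  cached("design", optimize_design(study_schema_t(), study_prior_t(),
                                   n_sets = 54L, n_varying_max = 5L,
                                   n_blocks = 3L, restarts = 4L, seed = 42L))
}

study_truth_t <- function() cached("truth", study_truth_default(study_schema_t()))

study_spec_t <- function() {
  cached("spec", spec_from_truth(study_schema_t(), study_truth_t()))
}

study_dataset_t <- function() {
  cached("dataset", {
    pop <- generate_population(547L, seed = 2L)
    simulate_choices(study_design_t(), pop, study_truth_t(), seed = 5L)
  })
}

study_fit_t <- function() {
  cached("fit", fit_mnl(study_dataset_t(), study_spec_t()))
}

study_lr_t <- function() {
  cached("lr", lr_table(study_dataset_t(), study_spec_t(), study_fit_t()))
}

# a small optimized design + main-effects truth for estimation tests
toy_fit_fixture <- function() {
  cached("toyfit", {
    sch <- toy_schema(4)
    pr <- build_ordered_prior(sch, draws = 64L, seed = 3L)
    des <- optimize_design(sch, pr, n_sets = 10L, n_varying_max = 3L,
                           restarts = 2L, seed = 4L)
    base <- setNames(c(0.5, 0.1, -0.3, 0.05, 0.2, 0, 0.4, -0.1),
                     coding_map(sch)$column)
    truth <- truth_spec(base, completion = 0.9)
    pop <- generate_population(120L, seed = 7L, n_blocks = 1L)
    ds <- simulate_choices(des, pop, truth, seed = 8L)
    list(schema = sch, prior = pr, design = des, base = base,
         truth = truth, population = pop, dataset = ds,
         spec = model_spec(sch))
  })
}

# True coefficients of the fitted (covariate-centered) parameterization:
# main effects absorb mean(z) times each interaction offset; interaction
# slopes are the offsets themselves (binary covariates, scale 1).
true_beta_centered <- function(fit, truth, schema) {
  ids <- schema_ids_t(schema)
  beta <- truth$base
  tf <- fit$covariate_transforms
  inter <- numeric(0)
  for (tr in truth$interactions) {
    k <- match(tr$attribute, ids)
    cols <- c(2L * k - 1L, 2L * k)
    ctr <- tf$center[match(tr$covariate, tf$covariate)]
    beta[cols] <- beta[cols] + ctr * tr$offsets[1:2]
    inter <- c(inter, tr$offsets[1:2])
  }
  unname(c(beta, inter))
}

schema_ids_t <- function(schema) schema$attributes$id

# Published predicted total utilities by area and stakeholder group,
# before and after the proposed payment reform, with the printed relative
# difference (display inputs for arithmetic checks).
printed_table3 <- function() {
  rows <- rbind(
    c("canada", "physician", 0.61, 0.48, -0.21),
    c("canada", "policy_maker", -0.04, 0.82, 21.50),
    c("canada", "executive", 0.37, 0.48, 0.30),
    c("canada", "researcher", 0.42, 1.18, 1.81),
    c("oceania", "physician", 1.57, 1.18, -0.25),
    c("oceania", "policy_maker", 0.92, 1.52, 0.65),
    c("oceania", "executive", 1.33, 1.18, -0.11),
    c("oceania", "researcher", 1.38, 1.88, 0.36),
    c("eastern_europe", "physician", 0.22, 1.40, 5.36),
    c("eastern_europe", "policy_maker", -0.43, 1.74, 4.05),
    c("eastern_europe", "executive", -0.02, 1.40, 70.00),
    c("eastern_europe", "researcher", 0.03, 2.10, 69.00),
    c("western_europe", "physician", 0.96, 0.80, -0.17),
    c("western_europe", "policy_maker", 0.31, 1.14, 2.68),
    c("western_europe", "executive", 0.72, 0.80, 0.11),
    c("western_europe", "researcher", 0.77, 1.50, 0.95),
    c("us", "physician", 1.00, 1.23, 0.23),
    c("us", "policy_maker", 0.35, 1.57, 3.49),
    c("us", "executive", 0.76, 1.23, 0.62),
    c("us", "researcher", 0.81, 1.93, 1.38))
  data.frame(area = rows[, 1], role = rows[, 2],
             before = as.numeric(rows[, 3]), after = as.numeric(rows[, 4]),
             printed = as.numeric(rows[, 5]), stringsAsFactors = FALSE)
}

# independent straight-loop information-matrix oracle
info_matrix_oracle <- function(design, beta) {
  p <- length(beta)
  M <- matrix(0, p, p)
  for (set in design$sets) {
    x1 <- effects_code(design$schema, set$profiles[[1L]])
    x2 <- effects_code(design$schema, set$profiles[[2L]])
    e1 <- exp(sum(x1 * beta))
    e2 <- exp(sum(x2 * beta))
    p1 <- e1 / (e1 + e2)
    p2 <- e2 / (e1 + e2)
    X <- rbind(x1, x2)
    W <- rbind(c(p1 - p1^2, -p1 * p2), c(-p1 * p2, p2 - p2^2))
    M <- M + t(X) %*% W %*% X
  }
  unname(M)
}
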