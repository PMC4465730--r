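#' Target margins of the study population
#'
#' Marginal frequencies of the respondent characteristics emulated by the
#' synthetic-population generator: overlapping stakeholder roles, one
#' geographical area, sex, age and seniority (means and SDs of truncated
#' normals), and the payment forms currently in use. Values follow the
#' study's respondent table (547 participants).
#'
#' @return A list of margin specifications accepted by
#'   [generate_population()].
#' @export
study_margins <- function() {
  list(
    roles = c(physician = 0.67, policy_maker = 0.22, executive = 0.34,
              researcher = 0.30),
    area = c(canada = 0.10, eastern_europe = 0.09, western_europe = 0.25,
             oceania = 0.18, us = 0.37),
    female = 0.31,
    age_mean = 50, age_sd = 11, age_range = c(25, 80),
    seniority_mean = 23, seniority_sd = 11, seniority_range = c(0, 60),
    payment_systems = c(salary = 0.67, fee_for_service = 0.60,
                        episode_based = 0.06, capitation = 0.16,
                        quality_bonus = 0.16,
                        evidence_informed_case_rate = 0.02,
                        never_event_warranty = 0.01)
  )
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate a synthetic respondent population
#'
#' Characteristics are sampled independently with the given margins: roles
#' as independent Bernoulli indicators, redrawn while a respondent has no
#' role (every participant holds at least one) with sampling probabilities
#' deflated so the post-rejection shares still match the targets; one area per
#' respondent, sex as Bernoulli, age and seniority as truncated normals
#' with seniority clamped to not exceed age, and payment forms as
#' independent Bernoulli indicators. Survey blocks are assigned cyclically
#' so each block is filled about equally often.
#'
#' @param n Number of respondents.
#' @param margins Margin list as returned by [study_margins()].
#' @param seed Integer seed.
#' @param n_blocks Number of survey blocks respondents cycle through.
#' @return A data.frame with one row per respondent: `id`, role indicators,
#'   `area` plus area indicator columns, `female`, `age`, `seniority`,
#'   payment-form indicators, `block`.
#' @export
generate_population <- function(n, margins = study_margins(), seed = 1L,
                                n_blocks = 3L) {
  stopifnot(n >= 1)
  probs <- c(margins$roles, margins$area, female = margins$female,
             margins$payment_systems)
  if (any(probs < 0 | probs > 1)) stop("margins must lie in [0, 1]")
  if (abs(sum(margins$area) - 1) > 0.05) {
    stop("area margins must sum to (approximately) 1")
  }
  if (sum(margins$roles) <= 0) {
    stop("at least one role margin must be positive")
  }
  margins$area <- margins$area / sum(margins$area)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # Respondents with no role are redrawn, which would inflate the realized
  # role shares; deflate the sampling probabilities to the fixed point
  # p' = p * (1 - q), q = prod(1 - p'), so post-rejection margins hit the
  # targets.
  p_roles <- margins$roles
  for (it in 1:50) {
    q <- prod(1 - p_roles)
    p_new <- pmin(margins$roles * (1 - q), 1)
    if (max(abs(p_new - p_roles)) < 1e-12) break
    p_roles <- p_new
  }
  roles <- sapply(p_roles, function(p) rbinom(n, 1L, p))
  roles <- matrix(roles, nrow = n,
                  dimnames = list(NULL, names(margins$roles)))
  none <- rowSums(roles) == 0L
  while (any(none)) {
    roles[none, ] <- sapply(p_roles, function(p) rbinom(sum(none), 1L, p))
    none <- rowSums(roles) == 0L
  }
  area <- sample(names(margins$area), n, replace = TRUE,
                 prob = margins$area)
  age <- rtruncnorm(n, margins$age_mean, margins$age_sd,
                    margins$age_range[1L], margins$age_range[2L])
  seniority <- rtruncnorm(n, margins$seniority_mean, margins$seniority_sd,
                          margins$seniority_range[1L],
                          margins$seniority_range[2L])
  seniority <- pmin(seniority, age)
  pay <- sapply(margins$payment_systems, function(p) rbinom(n, 1L, p))
  pay <- matrix(pay, nrow = n,
                dimnames = list(NULL, names(margins$payment_systems)))
  out <- data.frame(id = seq_len(n), roles, area = area,
                    female = rbinom(n, 1L, margins$female),
                    age = age, seniority = seniority, pay,
                    block = rep_len(seq_len(n_blocks), n),
                    stringsAsFactors = FALSE)
  for (a in names(margins$area)) {
    out[[paste0("area_", a)]] <- as.integer(out$area == a)
  }
  out
}

#' Data-generating truth for the choice simulator
#'
#' @param base Named coefficient vector over the coding-map columns
#'   (main-effect utilities in effects-coded space).
#' @param interactions List of interaction offsets; each element a list
#'   with `covariate` (a respondent column), `attribute`, and `offsets`,
#'   the level-utility offsets `(positive, no_change, negative)` that must
#'   sum to zero.
#' @param completion Probability in (0, 1] that a shown choice set is
#'   answered.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(base, interactions = list(), completion = 1) {
  stopifnot(completion > 0, completion <= 1)
  for (tr in interactions) {
    if (!all(c("covariate", "attribute", "offsets") %in% names(tr))) {
      stop("each interaction needs covariate, attribute and offsets")
    }
    if (length(tr$offsets) != 3L || abs(sum(tr$offsets)) > 1e-8) {
      stop("interaction offsets must be 3 level utilities summing to zero")
    }
  }
  structure(list(base = base, interactions = interactions,
                 completion = completion),
            class = "truth_spec")
}

# truth level-utility table (K x 3) implied by the base coefficients
truth_level_table <- function(schema, truth) {
  t(vapply(schema_ids(schema),
           function(a) level_utilities(schema, truth$base, a), numeric(3)))
}

#' Default data-generating truth emulating the study's headline pattern
#'
#' Marginal utilities follow the reported qualitative structure: a
#' deterioration in clinical effectiveness and patient safety is by far the
#' strongest driver (utility -1, the standardization reference), avoiding a
#' negative outcome outweighs attaining a positive one for every domain
#' except long-term cost containment and gaming (where improvement
#' dominates), and status-quo outcomes matter little, mostly positively
#' (slightly negatively for long-term cost containment and gaming).
#' Subgroup offsets carry the reported signs: physicians weight provider
#' wellness, effectiveness, coordination and timeliness up and short-term
#' cost containment down; policy makers weight gaming improvement up and
#' gaming avoidance down; executives weight provider wellness up;
#' researchers weight effectiveness and long-term cost containment up; and
#' the geographic offsets make Oceania and the US most, Canada least,
#' sensitive to effectiveness, with Eastern Europe and Canada favoring
#' improvement over avoidance in that domain.
#'
#' Magnitudes are scaled so the pre-standardization reference utility is
#' -1, making standardized outputs directly comparable to the truth. The
#' completion probability is 0.87.
#'
#' @param schema The study schema from [build_schema()].
#' @return A `truth_spec`.
#' @export
study_truth_default <- function(schema) {
  util <- rbind(
    effectiveness_safety = c(0.87, 0.13, -1.00),
    best_practice        = c(0.45, 0.05, -0.50),
    care_equity          = c(0.20, 0.04, -0.24),
    coordination         = c(0.38, 0.05, -0.43),
    patient_centeredness = c(0.28, 0.04, -0.32),
    timeliness           = c(0.22, 0.04, -0.26),
    short_term_cost      = c(0.18, 0.03, -0.21),
    long_term_cost       = c(0.58, -0.05, -0.53),
    provider_wellness    = c(0.32, 0.05, -0.37),
    innovation           = c(0.30, 0.04, -0.34),
    gaming               = c(0.24, -0.04, -0.20)
  )
  ids <- schema_ids(schema)
  if (!setequal(rownames(util), ids)) {
    stop("study_truth_default requires the default study schema")
  }
  util <- util[ids, , drop = FALSE]
  base <- setNames(utilities_to_beta(schema, util), coding_map(schema)$column)
  inter <- list(
    list(covariate = "physician", attribute = "effectiveness_safety",
         offsets = c(0.05, 0.08, -0.13)),
    list(covariate = "physician", attribute = "coordination",
         offsets = c(0.12, -0.04, -0.08)),
    list(covariate = "physician", attribute = "provider_wellness",
         offsets = c(0.15, -0.02, -0.13)),
    list(covariate = "physician", attribute = "timeliness",
         offsets = c(0.10, -0.02, -0.08)),
    list(covariate = "physician", attribute = "short_term_cost",
         offsets = c(-0.06, 0.02, 0.04)),
    list(covariate = "policy_maker", attribute = "gaming",
         offsets = c(0.14, -0.17, 0.03)),
    list(covariate = "executive", attribute = "provider_wellness",
         offsets = c(0.10, -0.02, -0.08)),
    list(covariate = "researcher", attribute = "effectiveness_safety",
         offsets = c(0.12, 0.03, -0.15)),
    list(covariate = "researcher", attribute = "long_term_cost",
         offsets = c(0.20, -0.05, -0.15)),
    list(covariate = "area_oceania", attribute = "effectiveness_safety",
         offsets = c(0.14, -0.02, -0.12)),
    list(covariate = "area_canada", attribute = "effectiveness_safety",
         offsets = c(-0.10, 0.04, 0.06)),
    list(covariate = "area_eastern_europe",
         attribute = "effectiveness_safety",
         offsets = c(0.10, -0.16, 0.06)),
    list(covariate = "area_us", attribute = "effectiveness_safety",
         offsets = c(0.10, -0.02, -0.08))
  )
  truth_spec(base, inter, completion = 0.87)
}

# coefficient vector of one respondent under a truth spec
respondent_beta <- function(schema, truth, respondent) {
  beta <- truth$base
  ids <- schema_ids(schema)
  for (tr in truth$interactions) {
    z <- respondent[[tr$covariate]]
    if (is.null(z)) stop("truth covariate '", tr$covariate,
                         "' absent from respondent table")
    if (z == 0) next
    k <- match(tr$attribute, ids)
    cols <- c(2L * k - 1L, 2L * k)
    beta[cols] <- beta[cols] + z * tr$offsets[1:2]
  }
  beta
}

#' Simulate choice data from a design, a population and a truth
#'
#' Each respondent sees the choice sets of their survey block. Every shown
#' set is answered independently with the truth's completion probability;
#' unanswered sets are dropped entirely (both alternatives). For an
#' answered set, alternative 1 is chosen with multinomial-logit probability
#' `exp(u1) / (exp(u1) + exp(u2))`, where the utilities sum the
#' respondent-specific marginal utilities (base plus applicable interaction
#' offsets) of the coded profiles.
#'
#' @param design A `choice_design`.
#' @param population Respondent data.frame from [generate_population()].
#' @param truth A `truth_spec`.
#' @param seed Integer seed.
#' @return An object of class `choice_dataset`: list with `respondents`,
#'   `observations` (long format: `respondent_id`, `set_id`, `alt`, one
#'   level column per attribute, `chosen`) and `schema`.
#' @export
simulate_choices <- function(design, population, truth, seed = 1L) {
  schema <- design$schema
  ids <- schema_ids(schema)
  if (length(truth$base) != 2L * length(ids)) {
    stop("truth base coefficient dimension does not match the schema")
  }
  if (any(!population$block %in% design$blocks)) {
    stop("population references a survey block absent from the design")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  D <- design_diff_matrix(design)
  set_ids <- vapply(design$sets, function(s) s$id, design$sets[[1L]]$id)
  lev1 <- do.call(rbind, lapply(design$sets, function(s) s$profiles[[1L]]))
  lev2 <- do.call(rbind, lapply(design$sets, function(s) s$profiles[[2L]]))
  by_block <- split(seq_along(design$sets),
                    design$blocks[as.character(set_ids)])
  out <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    resp <- population[i, ]
    rows <- by_block[[as.character(resp$block)]]
    answered <- rows[runif(length(rows)) <= truth$completion]
    if (length(answered) == 0L) { out[[i]] <- NULL; next }
    beta <- respondent_beta(schema, truth, resp)
    eta <- drop(D[answered, , drop = FALSE] %*% beta)
    pick1 <- runif(length(answered)) <= plogis(eta)
    lv <- rbind(lev1[answered, , drop = FALSE],
                lev2[answered, , drop = FALSE])
    out[[i]] <- data.frame(
      respondent_id = resp$id,
      set_id = rep(set_ids[answered], 2L),
      alt = rep(1:2, each = length(answered)),
      as.data.frame(lv, stringsAsFactors = FALSE),
      chosen = as.integer(c(pick1, !pick1)),
      stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  structure(list(respondents = population, observations = obs,
                 schema = schema),
            class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat("Choice dataset:", nrow(x$respondents), "respondents,",
      nrow(x$observations) / 2, "answered choice sets\n")
  invisible(x)
}

#' Completion summary of a dataset
#'
#' @param dataset A `choice_dataset`.
#' @param sets_per_respondent Number of choice sets shown to each
#'   respondent (one survey block).
#' @return List with `shown`, `answered` and `completion_rate` (percent).
#' @export
completion_summary <- function(dataset, sets_per_respondent) {
  shown <- nrow(dataset$respondents) * sets_per_respondent
  answered <- nrow(dataset$observations) / 2L
  list(shown = shown, answered = answered,
       completion_rate = 100 * answered / shown)
}

#' Write / read choice data as a pair of CSV files
#'
#' `respondents.csv` holds the covariate table; `choices.csv` the long
#' observations (respondent id, set id, alternative, level labels, chosen
#' flag). The round trip is loss-free up to level-label normalization.
#'
#' @param dataset A `choice_dataset`.
#' @param respondents_path,choices_path File paths.
#' @param schema Schema used to re-validate levels on read.
#' @return `write_choice_data` invisibly returns the paths;
#'   `read_choice_data` returns a `choice_dataset`.
#' @export
write_choice_data <- function(dataset, respondents_path, choices_path) {
  write.csv(dataset$respondents, respondents_path, row.names = FALSE)
  obs <- dataset$observations
  for (a in schema_ids(dataset$schema)) obs[[a]] <- SHORT_LEVELS[obs[[a]]]
  write.csv(obs, choices_path, row.names = FALSE)
  invisible(c(respondents_path, choices_path))
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(respondents_path, choices_path, schema) {
  respondents <- read.csv(respondents_path, stringsAsFactors = FALSE)
  obs <- read.csv(choices_path, stringsAsFactors = FALSE)
  for (a in schema_ids(schema)) {
    if (!a %in% names(obs)) stop("choices file missing level column '", a, "'")
    obs[[a]] <- normalize_level(obs[[a]])
  }
  structure(list(respondents = respondents, observations = obs,
                 schema = schema),
            class = "choice_dataset")
}
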