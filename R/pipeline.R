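#' Default end-to-end run configuration
#'
#' Study-scale defaults: 11-attribute schema, ordered prior, 54 choice sets
#' in 3 survey blocks with at most 5 varying attributes, 547 respondents
#' with an 87% completion rate, a model mirroring the default truth's
#' interaction structure, and the payment-reform scenario.
#'
#' @param outdir Output directory.
#' @param seed Root seed; every stage derives its own recorded seed from
#'   it.
#' @return A run-configuration list accepted by [run_pipeline()].
#' @export
default_run_config <- function(outdir = tempfile("ppdce_run"), seed = 1L) {
  list(
    schema = NULL,  # NULL -> default study schema
    prior = list(base_gap = 1, loss_aversion = 1.5, rank_decay = 0.9,
                 sd = 0.5, draws = 256L),
    design = list(n_sets = 54L, n_varying_max = 5L, n_blocks = 3L,
                  restarts = 4L),
    simulation = list(n_respondents = 547L, completion = 0.87),
    scenario = NULL,  # NULL -> default reform scenario
    seed = as.integer(seed),
    outdir = outdir
  )
}

#' Run the full design-simulate-fit-report-scenario pipeline
#'
#' Executes all stages in order, writing every intermediate artifact to the
#' configured output directory: `prior.json`, `design.csv`,
#' `design_report.json`, `respondents.csv`, `choices.csv`, `fit.json`,
#' `importance.csv`, `utilities.csv` and `scenario_report.csv`, plus a
#' `manifest.json` recording files, per-stage seeds, the design criterion,
#' the fitted log-likelihood and convergence flags. Deterministic given an
#' identical configuration. A stage failure halts the run with the stage
#' name attached to the error.
#'
#' @param config Run-configuration list (see [default_run_config()]) or a
#'   path to a YAML file holding one.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  config <- modifyList(base, config)
  if (is.character(config$schema) && !file.exists(config$schema)) {
    stop("run config invalid: schema file '", config$schema,
         "' does not exist")
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(design = derive_seed(config$seed, 1L),
                population = derive_seed(config$seed, 2L),
                choices = derive_seed(config$seed, 3L))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  path <- function(f) file.path(config$outdir, f)

  schema <- stage("schema", build_schema(config$schema))
  prior <- stage("prior", do.call(build_ordered_prior, c(
    list(schema = schema, seed = seeds$design), config$prior)))
  prior_to_json(prior, path("prior.json"))

  design <- stage("design", do.call(optimize_design, c(
    list(schema = schema, prior = prior, seed = seeds$design),
    config$design)))
  write_design_csv(design, path("design.csv"))
  design_report(design, path = path("design_report.json"))

  truth <- stage("truth", {
    tr <- study_truth_default(schema)
    tr$completion <- config$simulation$completion
    tr
  })
  pop <- stage("population", generate_population(
    config$simulation$n_respondents, seed = seeds$population,
    n_blocks = config$design$n_blocks))
  dataset <- stage("simulate", simulate_choices(design, pop, truth,
                                                seed = seeds$choices))
  write_choice_data(dataset, path("respondents.csv"), path("choices.csv"))

  spec <- spec_from_truth(schema, truth)
  fit <- stage("fit", fit_mnl(dataset, spec))
  lrt <- stage("lr_tests", lr_table(dataset, spec, fit))
  write_fit_json(fit, path("fit.json"), lr = lrt)
  imp <- importance_table(lrt)
  write.csv(imp, path("importance.csv"), row.names = FALSE)

  contexts <- c(list(pooled = list()), area_role_contexts())
  std <- stage("standardize", standardize_utilities(fit, schema, contexts))
  write.csv(std, path("utilities.csv"), row.names = FALSE)

  scen <- stage("scenario", if (is.null(config$scenario)) {
    reform_scenario_default(schema)
  } else if (is.character(config$scenario)) {
    read_scenario_yaml(config$scenario, schema)
  } else {
    scenario(config$scenario$name %||% "scenario",
             config$scenario$outcomes, schema)
  })
  rep3 <- utility_report(std, scen, schema)
  write.csv(rep3, path("scenario_report.csv"), row.names = FALSE)

  manifest <- list(
    files = c("prior.json", "design.csv", "design_report.json",
              "respondents.csv", "choices.csv", "fit.json",
              "importance.csv", "utilities.csv", "scenario_report.csv"),
    seeds = seeds,
    criterion_value = design$criterion_value,
    design_converged = isTRUE(design$converged),
    log_likelihood = fit$log_likelihood,
    fit_converged = fit$converged,
    n_respondents = nrow(pop),
    n_answered_sets = fit$n_choice_sets
  )
  jsonlite::write_json(manifest, path("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Validate a choice dataset against its design
#'
#' Checks the structural invariants of long-format choice data: every
#' (respondent, set) pair has exactly two alternative rows with exactly one
#' chosen; level labels are legal (normalized with a warning when they
#' differ only by case/whitespace); each answered set belongs to the
#' respondent's survey block; and the level configuration matches the
#' design's profiles.
#'
#' @param choices_file,respondents_file,design_file CSV paths as written by
#'   [write_choice_data()] and [write_design_csv()].
#' @param schema A `dce_schema`.
#' @return Data.frame of violations (`check`, `detail`); zero rows when the
#'   dataset is valid.
#' @export
validate_dataset <- function(choices_file, respondents_file, design_file,
                             schema) {
  choices <- read.csv(choices_file, stringsAsFactors = FALSE)
  respondents <- read.csv(respondents_file, stringsAsFactors = FALSE)
  design <- read_design_csv(design_file, schema)
  ids <- schema_ids(schema)
  bad <- list()
  note <- function(check, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  raw_levels <- unlist(choices[, intersect(ids, names(choices))])
  dirty <- raw_levels[!raw_levels %in% names(LEVEL_ALIASES)]
  if (length(dirty)) {
    cleanable <- tolower(trimws(dirty)) %in% names(LEVEL_ALIASES)
    if (any(cleanable)) {
      warning("normalized ", sum(cleanable),
              " level label(s) differing by case/whitespace")
    }
    if (any(!cleanable)) {
      note("levels", paste("illegal level label(s):",
                           paste(unique(dirty[!cleanable]), collapse = ", ")))
    }
  }
  for (a in intersect(ids, names(choices))) {
    ok <- tolower(trimws(choices[[a]])) %in% names(LEVEL_ALIASES)
    choices[[a]][!ok] <- "nc"  # placeholder so later checks can proceed
    choices[[a]] <- normalize_level(choices[[a]])
  }
  missing_cols <- setdiff(ids, names(choices))
  if (length(missing_cols)) {
    note("columns", paste("missing level column(s):",
                          paste(missing_cols, collapse = ", ")))
    return(do.call(rbind, bad))
  }
  key <- paste(choices$respondent_id, choices$set_id)
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) != 2L || !setequal(choices$alt[rows], 1:2)) {
      note("pairing", paste("set", k, "does not have alternatives 1 and 2",
                            "(rows", paste(rows, collapse = ","), ")"))
      next
    }
    nchosen <- sum(choices$chosen[rows])
    if (nchosen != 1L) {
      note("choice", paste("set", k, "has", nchosen,
                           "chosen alternatives (rows",
                           paste(rows, collapse = ","), ")"))
    }
  }
  set_block <- design$blocks
  ridx <- match(choices$respondent_id, respondents$id)
  if (anyNA(ridx)) {
    note("respondents", "choices reference respondents absent from the table")
  } else if ("block" %in% names(respondents)) {
    blk <- respondents$block[ridx]
    dblk <- set_block[as.character(choices$set_id)]
    off <- which(!is.na(dblk) & blk != dblk)
    if (length(off)) {
      note("blocks", paste("rows answered outside their survey block:",
                           paste(utils::head(off, 10L), collapse = ",")))
    }
  }
  # level configuration must match the design profile
  dsets <- setNames(design$sets, vapply(design$sets, function(s)
    as.character(s$id), ""))
  for (i in seq_len(nrow(choices))) {
    set <- dsets[[as.character(choices$set_id[i])]]
    if (is.null(set)) {
      note("design", paste("unknown set id", choices$set_id[i]))
      next
    }
    prof <- set$profiles[[choices$alt[i]]]
    got <- unlist(choices[i, ids])
    if (!all(got == prof[ids])) {
      note("profiles", paste("row", i, "levels differ from design set",
                             choices$set_id[i], "alternative",
                             choices$alt[i]))
    }
  }
  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(check = character(), detail = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
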