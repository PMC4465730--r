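#' Define an outcome scenario
#'
#' A scenario assigns one outcome level to every attribute; the status-quo
#' scenario sets every attribute to `no_change`.
#'
#' @param name Scenario name.
#' @param outcomes Named character vector / list mapping every attribute id
#'   to an outcome level.
#' @param schema Schema the scenario must cover.
#' @return An object of class `dce_scenario`.
#' @export
scenario <- function(name, outcomes, schema) {
  ids <- schema_ids(schema)
  outcomes <- unlist(outcomes)
  missing <- setdiff(ids, names(outcomes))
  if (length(missing)) {
    stop("scenario '", name, "' missing outcome for: ",
         paste(missing, collapse = ", "))
  }
  structure(list(name = name,
                 outcomes = setNames(normalize_level(outcomes[ids]), ids)),
            class = "dce_scenario")
}

#' @rdname scenario
#' @export
status_quo_scenario <- function(schema) {
  scenario("status_quo",
           setNames(rep("no_change", length(schema_ids(schema))),
                    schema_ids(schema)), schema)
}

#' Default payment-reform scenario
#'
#' The value-based reform configuration: improvements in clinical
#' effectiveness and patient safety, long-term cost containment, best
#' practice service use, coordination and innovation; unintended
#' deterioration in provider wellness, patient centeredness, timeliness,
#' gaming and short-term cost containment; and a status quo in care
#' equity.
#'
#' @param schema The study schema.
#' @return A `dce_scenario`.
#' @export
reform_scenario_default <- function(schema) {
  out <- c(
    effectiveness_safety = "positive", long_term_cost = "positive",
    best_practice = "positive", coordination = "positive",
    innovation = "positive",
    provider_wellness = "negative", patient_centeredness = "negative",
    timeliness = "negative", gaming = "negative",
    short_term_cost = "negative",
    care_equity = "no_change"
  )
  scenario("payment_reform", out, schema)
}

#' Read a scenario from a YAML document
#'
#' Expects `name` plus an `outcomes` mapping of attribute id to level.
#'
#' @param path YAML file path.
#' @param schema Schema the scenario must cover.
#' @return A `dce_scenario`.
#' @export
read_scenario_yaml <- function(path, schema) {
  obj <- yaml::read_yaml(path)
  scenario(obj$name %||% "scenario", obj$outcomes, schema)
}

#' Total utility of a scenario for one subgroup context
#'
#' Sums, over all attributes, the context's standardized marginal utility
#' at the scenario's outcome level. For the status-quo scenario this adds
#' up the no-change utilities of every attribute.
#'
#' @param utilities A `standardized_utilities` table.
#' @param scen A `dce_scenario`.
#' @param context Context name present in `utilities`.
#' @return Scalar total utility.
#' @export
total_utility <- function(utilities, scen, context = "pooled") {
  sub <- utilities[utilities$context == context, ]
  if (nrow(sub) == 0L) stop("context '", context, "' absent from utilities")
  key <- paste(sub$attribute, sub$level)
  want <- paste(names(scen$outcomes), scen$outcomes)
  idx <- match(want, key)
  if (anyNA(idx)) {
    stop("missing utility for ", paste(want[is.na(idx)], collapse = ", "))
  }
  sum(sub$utility[idx])
}

#' Relative difference between two total utilities
#'
#' `(u_after - u_before) / u_before`: the change in total utility induced
#' by a reform, expressed relative to the status-quo total. Reports round
#' to 2 decimals. When the baseline is negative the ratio's sign is not
#' interpretable on its own; consumers should carry a baseline-sign flag
#' (as [utility_report()] does).
#'
#' @param u_before Status-quo total utility (nonzero).
#' @param u_after Post-reform total utility.
#' @return The raw relative difference.
#' @export
#' @examples
#' round_half_up(relative_difference(0.61, 0.48), 2)  # -0.21
relative_difference <- function(u_before, u_after) {
  if (u_before == 0) stop("relative difference undefined for a zero baseline")
  (u_after - u_before) / u_before
}

#' Named subgroup contexts for every area x role cell
#'
#' Builds the context list consumed by [standardize_utilities()]: each cell
#' sets the focal stakeholder-role indicator to 1 (other, overlapping roles
#' stay at their population mean) and the five mutually exclusive area
#' indicators to the cell's area, combining main effects with role and
#' area offsets additively; no area-by-role interaction terms are used.
#'
#' @param areas Area ids (indicator columns are `area_<id>`).
#' @param roles Role indicator column names.
#' @return Named list of contexts, names `"<area>.<role>"`.
#' @export
area_role_contexts <- function(areas = c("canada", "oceania",
                                         "eastern_europe", "western_europe",
                                         "us"),
                               roles = c("physician", "policy_maker",
                                         "executive", "researcher")) {
  ctx <- list()
  for (a in areas) {
    for (r in roles) {
      cell <- setNames(as.list(as.integer(areas == a)),
                       paste0("area_", areas))
      cell[[r]] <- 1
      ctx[[paste(a, r, sep = ".")]] <- cell
    }
  }
  ctx
}

#' Predicted total utility by subgroup, before and after a reform
#'
#' For every area x role context present in the utilities table, computes
#' the total utility of the status quo, the total utility of the reform
#' scenario, and their relative difference (rounded to 2 decimals,
#' half-up). Rows with a negative status-quo baseline are flagged because
#' the relative difference's sign is not interpretable there.
#'
#' @param utilities A `standardized_utilities` table whose context names
#'   follow `"<area>.<role>"` (see [area_role_contexts()]).
#' @param scen Reform scenario.
#' @param schema Schema (for the status-quo scenario).
#' @return Data.frame of class `utility_report`: `area`, `role`,
#'   `u_status_quo`, `u_scenario`, `relative_difference`,
#'   `baseline_negative`.
#' @export
utility_report <- function(utilities, scen, schema) {
  sq <- status_quo_scenario(schema)
  ctx_names <- unique(utilities$context)
  ctx_names <- ctx_names[grepl(".", ctx_names, fixed = TRUE)]
  parts <- strsplit(ctx_names, ".", fixed = TRUE)
  rows <- lapply(seq_along(ctx_names), function(i) {
    u0 <- total_utility(utilities, sq, ctx_names[i])
    u1 <- total_utility(utilities, scen, ctx_names[i])
    data.frame(area = parts[[i]][1L], role = parts[[i]][2L],
               u_status_quo = u0, u_scenario = u1,
               relative_difference = round_half_up(
                 relative_difference(u0, u1), 2L),
               baseline_negative = u0 < 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("utility_report", "data.frame")
  out
}

#' Goal alignment between two stakeholder roles, by area
#'
#' Compares the absolute total-utility gap between two roles under the
#' status quo and under the reform scenario; the gap has narrowed when it
#' is strictly smaller under the scenario.
#'
#' @param report A `utility_report`.
#' @param role_a,role_b Role names present in the report.
#' @return Data.frame: `area`, `gap_status_quo`, `gap_scenario`,
#'   `narrowed`.
#' @export
alignment_change <- function(report, role_a, role_b) {
  if (!all(c(role_a, role_b) %in% report$role)) {
    stop("both roles must be present in the report")
  }
  areas <- unique(report$area)
  rows <- lapply(areas, function(ar) {
    ra <- report[report$area == ar & report$role == role_a, ]
    rb <- report[report$area == ar & report$role == role_b, ]
    if (nrow(ra) != 1L || nrow(rb) != 1L) {
      stop("missing role rows for area '", ar, "'")
    }
    g0 <- abs(ra$u_status_quo - rb$u_status_quo)
    g1 <- abs(ra$u_scenario - rb$u_scenario)
    data.frame(area = ar, gap_status_quo = g0, gap_scenario = g1,
               narrowed = g1 < g0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
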