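#' @useDynLib ppdce, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate optim pchisq plogis pnorm qnorm rbinom rnorm
#'   runif setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Canonical outcome-level labels, in display order.
DCE_LEVELS <- c("positive", "no_change", "negative")

# Accepted aliases when reading external files (case-insensitive, trimmed).
LEVEL_ALIASES <- c(
  positive = "positive", pos = "positive", "+" = "positive",
  no_change = "no_change", nc = "no_change", none = "no_change",
  status_quo = "no_change", negative = "negative", neg = "negative",
  "-" = "negative"
)

normalize_level <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(LEVEL_ALIASES[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown outcome level label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Build an attribute schema for a partial-profile choice experiment
#'
#' An attribute schema lists the attributes (here: health-system performance
#' domains) of the experiment, each with the three ordered outcome levels
#' `positive`, `no_change` and `negative`, an a-priori importance rank, and
#' the reference (attribute, level) pair used to standardize reported
#' utilities. Called without arguments it returns the default study
#' configuration: eleven performance domains ranked in their catalogued
#' order, with the reference pair set to a deterioration in clinical
#' effectiveness and patient safety.
#'
#' @param config Either `NULL` (study default), a path to a YAML/JSON
#'   document, or a list with elements `attributes` (each a list with `id`,
#'   `name`, `levels`, `rank`) and `reference` (list with `attribute`,
#'   `level`).
#' @return An object of class `dce_schema` with elements `attributes`
#'   (data.frame of `id`, `name`, `rank`), `levels`,
#'   `reference_attribute` and `reference_level`.
#' @export
#' @examples
#' sch <- build_schema()
#' sch$attributes$id
build_schema <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "study_schema.yaml", package = "ppdce")
  }
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$attributes)) {
    stop("schema config must be a list with an 'attributes' element")
  }
  atts <- config$attributes
  if (length(atts) < 2L) stop("schema validation error: need at least 2 attributes")
  ids <- vapply(atts, function(a) as.character(a$id %||% NA_character_), "")
  if (anyNA(ids) || any(ids == "")) stop("schema validation error: attribute missing 'id'")
  if (anyDuplicated(ids)) {
    stop("schema validation error: duplicate attribute id '",
         ids[duplicated(ids)][1L], "'")
  }
  for (a in atts) {
    lv <- unlist(a$levels %||% DCE_LEVELS)
    if (length(lv) != 3L || anyDuplicated(lv)) {
      stop("schema validation error: attribute '", a$id,
           "' must list exactly 3 distinct levels")
    }
    if (!setequal(normalize_level(lv), DCE_LEVELS)) {
      stop("schema validation error: attribute '", a$id,
           "' levels must be positive/no_change/negative")
    }
  }
  ranks <- vapply(atts, function(a) as.integer(a$rank %||% NA_integer_), 1L)
  if (anyNA(ranks)) ranks <- seq_along(atts)
  if (anyDuplicated(ranks)) {
    stop("schema validation error: importance ranks must be unique")
  }
  names_ <- vapply(atts, function(a) as.character(a$name %||% a$id), "")
  ref <- config$reference %||% list(attribute = ids[[1L]], level = "negative")
  ref_attr <- as.character(ref$attribute)
  ref_level <- normalize_level(ref$level)
  if (!ref_attr %in% ids) {
    stop("schema validation error: reference attribute '", ref_attr,
         "' absent from schema")
  }
  structure(
    list(
      attributes = data.frame(id = ids, name = names_, rank = ranks,
                              stringsAsFactors = FALSE),
      levels = DCE_LEVELS,
      reference_attribute = ref_attr,
      reference_level = ref_level
    ),
    class = "dce_schema"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dce_schema <- function(x, ...) {
  cat("Choice-experiment attribute schema:", nrow(x$attributes),
      "attributes x 3 outcome levels\n")
  cat("Reference pair:", x$reference_attribute, "/", x$reference_level, "\n")
  print(x$attributes, row.names = FALSE)
  invisible(x)
}

schema_ids <- function(schema) schema$attributes$id

#' Effects-coding map of a schema
#'
#' Each three-level attribute contributes two coefficient columns. The level
#' codes are `positive -> (1, 0)`, `no_change -> (0, 1)` and
#' `negative -> (-1, -1)`, so the three implied level utilities sum to zero
#' within every attribute and all three are reportable.
#'
#' @param schema A `dce_schema`.
#' @return A data.frame with one row per coefficient column: `column`,
#'   `attribute`, `component` (`pos` or `nc`).
#' @export
coding_map <- function(schema) {
  ids <- schema_ids(schema)
  data.frame(
    column = as.vector(rbind(paste0(ids, ".pos"), paste0(ids, ".nc"))),
    attribute = rep(ids, each = 2L),
    component = rep(c("pos", "nc"), length(ids)),
    stringsAsFactors = FALSE
  )
}

# per-level effects codes, rows in DCE_LEVELS order
EFFECTS_CODES <- matrix(c(1, 0, 0, 1, -1, -1), nrow = 3, byrow = TRUE,
                        dimnames = list(DCE_LEVELS, c("pos", "nc")))

#' Effects-code a profile
#'
#' Maps a complete profile (one outcome level per attribute) to its
#' coefficient-contribution vector under the schema's effects coding.
#'
#' @param schema A `dce_schema`.
#' @param profile Named character vector: `profile[[id]]` is the outcome
#'   level of attribute `id`. Must cover every schema attribute.
#' @return Named numeric vector of length `2 * K`.
#' @export
#' @examples
#' sch <- build_schema()
#' x <- effects_code(sch, setNames(rep("no_change", 11), sch$attributes$id))
effects_code <- function(schema, profile) {
  ids <- schema_ids(schema)
  if (!all(ids %in% names(profile))) {
    stop("profile is incomplete: missing ",
         paste(setdiff(ids, names(profile)), collapse = ", "))
  }
  lv <- normalize_level(unlist(profile[ids], use.names = FALSE))
  out <- as.vector(t(EFFECTS_CODES[lv, , drop = FALSE]))
  names(out) <- coding_map(schema)$column
  out
}

# Vectorized coding: `levels_df` has one column per attribute (level labels),
# one row per profile. Returns an n x 2K matrix.
effects_code_matrix <- function(schema, levels_df) {
  ids <- schema_ids(schema)
  n <- nrow(levels_df)
  out <- matrix(0, n, 2L * length(ids))
  colnames(out) <- coding_map(schema)$column
  for (k in seq_along(ids)) {
    lv <- normalize_level(levels_df[[ids[k]]])
    out[, 2L * k - 1L] <- EFFECTS_CODES[lv, 1L]
    out[, 2L * k] <- EFFECTS_CODES[lv, 2L]
  }
  out
}

#' Marginal utilities of the three outcome levels of one attribute
#'
#' Inverts the effects coding: given a coefficient vector, returns the
#' implied marginal utilities of the `positive`, `no_change` and `negative`
#' outcomes of one attribute. They sum to zero by construction.
#'
#' @param schema A `dce_schema`.
#' @param beta Coefficient vector of length `2 * K` (coding-map order).
#' @param attribute_id Attribute identifier.
#' @return Named numeric vector `(positive, no_change, negative)`.
#' @export
level_utilities <- function(schema, beta, attribute_id) {
  ids <- schema_ids(schema)
  k <- match(attribute_id, ids)
  if (is.na(k)) stop("unknown attribute id '", attribute_id, "'")
  if (length(beta) != 2L * length(ids)) {
    stop("beta has length ", length(beta), ", expected ", 2L * length(ids))
  }
  a <- beta[[2L * k - 1L]]
  b <- beta[[2L * k]]
  c(positive = a, no_change = b, negative = -a - b)
}

# Map per-attribute level utilities (pos, nc, neg summing to 0) to the two
# coded coefficients: trivially (a, b) = (u_pos, u_nc).
utilities_to_beta <- function(schema, util) {
  # util: K x 3 matrix, columns positive/no_change/negative
  stopifnot(ncol(util) == 3L)
  as.vector(t(util[, 1:2, drop = FALSE]))
}

#' Construct a choice set of two partial profiles
#'
#' @param id Choice-set identifier.
#' @param profile_1,profile_2 Named character vectors of outcome levels
#'   covering every schema attribute.
#' @param schema A `dce_schema`.
#' @param balanced_constants Attribute ids held constant by the attribute
#'   balance plan (the `*` constants).
#' @param incidental_constants Attribute ids free to vary that ended with
#'   equal levels in both profiles (the `SS` constants). If `NULL`, computed
#'   from the profiles.
#' @return A list of class `choice_set`.
#' @export
choice_set <- function(id, profile_1, profile_2, schema,
                       balanced_constants = character(),
                       incidental_constants = NULL) {
  ids <- schema_ids(schema)
  p1 <- setNames(normalize_level(unlist(profile_1[ids])), ids)
  p2 <- setNames(normalize_level(unlist(profile_2[ids])), ids)
  equal <- ids[p1 == p2]
  if (!all(balanced_constants %in% equal)) {
    stop("choice set ", id, ": planned constant attribute varies between profiles")
  }
  if (is.null(incidental_constants)) {
    incidental_constants <- setdiff(equal, balanced_constants)
  }
  if (length(intersect(balanced_constants, incidental_constants)) > 0L) {
    stop("choice set ", id, ": balanced and incidental constant sets overlap")
  }
  if (!all(incidental_constants %in% equal)) {
    stop("choice set ", id, ": incidental constant attribute varies between profiles")
  }
  structure(
    list(id = id, profiles = list(p1, p2),
         balanced_constant_ids = sort(balanced_constants),
         incidental_constant_ids = sort(incidental_constants)),
    class = "choice_set"
  )
}

n_varying <- function(set) {
  sum(set$profiles[[1L]] != set$profiles[[2L]])
}

#' Check whether one profile of a choice set dominates the other
#'
#' A choice set is dominated when one profile is at least as good as the
#' other on every attribute and strictly better on at least one, under a
#' stated preference ordering of the outcome levels. Dominated sets elicit
#' no trade-off information and are excluded from optimized designs.
#'
#' @param set A `choice_set`.
#' @param ordering Either a character vector of levels from best to worst,
#'   or a named numeric vector of level scores (higher preferred). Ties are
#'   allowed with numeric scores.
#' @return `TRUE` if either profile weakly dominates the other.
#' @export
dominance_check <- function(set, ordering = DCE_LEVELS) {
  if (is.character(ordering)) {
    score <- setNames(rev(seq_along(ordering)), normalize_level(ordering))
  } else {
    score <- setNames(as.numeric(ordering), normalize_level(names(ordering)))
  }
  s1 <- score[set$profiles[[1L]]]
  s2 <- score[set$profiles[[2L]]]
  d <- s1 - s2
  (all(d >= 0) && any(d > 0)) || (all(d <= 0) && any(d < 0))
}
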