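SHORT_LEVELS <- c(positive = "pos", no_change = "nc", negative = "neg")

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Plan which attributes are held constant in each choice set
#'
#' Partial profiles reduce respondent burden by varying at most
#' `n_varying_max` attributes per choice set; the remaining attributes are
#' held constant. The attribute balance approach holds each attribute
#' constant in an (as near as possible) equal number of choice sets and
#' pairs constant attributes approximately equally often. With 11
#' attributes, 54 sets and at most 5 varying attributes, every attribute is
#' planned constant in either 29 or 30 sets.
#'
#' The construction is a seeded randomized greedy: sets are filled by
#' descending remaining constancy quota, breaking ties by the smallest
#' pairwise co-constancy penalty; several internal restarts keep the
#' assignment with the most even pair counts.
#'
#' @param schema A `dce_schema`.
#' @param n_sets Number of choice sets.
#' @param n_varying_max Maximum number of varying attributes per set
#'   (between 2 and the number of attributes).
#' @param seed Integer seed.
#' @param max_tries Internal greedy restarts.
#' @return An object of class `balance_plan`: `assignment` (list of
#'   constant-attribute id vectors per set), `counts` (per-attribute
#'   constancy counts), `pair_counts` matrix, `pair_range`.
#' @export
plan_attribute_balance <- function(schema, n_sets, n_varying_max, seed = 1L,
                                   max_tries = 50L) {
  ids <- schema_ids(schema)
  K <- length(ids)
  if (n_varying_max > K) stop("n_varying_max exceeds the number of attributes")
  if (n_varying_max < 2L) stop("n_varying_max must be at least 2")
  stopifnot(n_sets >= 1L)
  n_const <- K - n_varying_max
  empty_pair <- matrix(0L, K, K, dimnames = list(ids, ids))
  if (n_const == 0L) {
    return(structure(list(assignment = rep(list(character()), n_sets),
                          counts = setNames(integer(K), ids),
                          pair_counts = empty_pair, pair_range = 0L,
                          n_sets = n_sets, n_varying_max = n_varying_max,
                          seed = as.integer(seed)),
                     class = "balance_plan"))
  }
  total <- n_sets * n_const
  base <- total %/% K
  extra <- total %% K
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  best <- NULL
  for (try in seq_len(max_tries)) {
    quota <- rep(base, K)
    if (extra > 0L) quota[sample.int(K, extra)] <- base + 1L
    remaining <- quota
    pair <- matrix(0L, K, K)
    assignment <- vector("list", n_sets)
    ok <- TRUE
    for (s in seq_len(n_sets)) {
      chosen <- integer(0)
      for (j in seq_len(n_const)) {
        cand <- setdiff(which(remaining > 0L), chosen)
        if (length(cand) == 0L) { ok <- FALSE; break }
        pen <- if (length(chosen))
          colSums(pair[chosen, cand, drop = FALSE]) else numeric(length(cand))
        pick <- cand[order(-remaining[cand], pen, runif(length(cand)))][1L]
        chosen <- c(chosen, pick)
        remaining[pick] <- remaining[pick] - 1L
      }
      if (!ok) break
      pair[chosen, chosen] <- pair[chosen, chosen] + 1L
      diag(pair) <- 0L
      assignment[[s]] <- ids[sort(chosen)]
    }
    if (!ok) next
    pr <- pair[upper.tri(pair)]
    score <- max(pr) - min(pr)
    if (is.null(best) || score < best$pair_range) {
      dimnames(pair) <- list(ids, ids)
      best <- list(assignment = assignment, counts = setNames(quota, ids),
                   pair_counts = pair, pair_range = score)
    }
    if (best$pair_range == 0L) break
  }
  if (is.null(best)) stop("attribute balance plan construction failed")
  structure(c(best, list(n_sets = n_sets, n_varying_max = n_varying_max,
                         seed = as.integer(seed))),
            class = "balance_plan")
}

#' @export
print.balance_plan <- function(x, ...) {
  cat("Attribute balance plan:", x$n_sets, "sets,",
      length(x$counts) - x$n_varying_max, "planned constants per set\n")
  cat("Constancy counts:", paste(x$counts, collapse = " "),
      "| pair-count range:", x$pair_range, "\n")
  invisible(x)
}

# ---- design container ------------------------------------------------------

new_choice_design <- function(schema, sets, blocks, n_varying_max,
                              criterion_value = NA_real_, plan = NULL,
                              converged = NA) {
  structure(list(schema = schema, sets = sets, blocks = blocks,
                 n_varying_max = n_varying_max,
                 criterion_value = criterion_value, plan = plan,
                 converged = converged),
            class = "choice_design")
}

#' @export
print.choice_design <- function(x, ...) {
  cat("Partial-profile choice design:", length(x$sets), "sets,",
      length(unique(x$blocks)), "block(s), <=", x$n_varying_max,
      "varying attributes per set\n")
  if (is.finite(x$criterion_value))
    cat("Bayesian D-criterion (mean log det):",
        format(x$criterion_value, digits = 6), "\n")
  invisible(x)
}

# n_sets x 2K matrix of effects-coded profile differences (profile 1 minus
# profile 2); the information matrix of a forced pair depends on the design
# only through these rows.
design_diff_matrix <- function(design) {
  schema <- design$schema
  l1 <- as.data.frame(do.call(rbind, lapply(design$sets, function(s)
    s$profiles[[1L]])), stringsAsFactors = FALSE)
  l2 <- as.data.frame(do.call(rbind, lapply(design$sets, function(s)
    s$profiles[[2L]])), stringsAsFactors = FALSE)
  effects_code_matrix(schema, l1) - effects_code_matrix(schema, l2)
}

#' Fisher information matrix of a paired-choice design under the MNL model
#'
#' `M(X, beta) = sum_s X_s' (diag(p_s) - p_s p_s') X_s`, where `X_s` stacks
#' the two effects-coded profiles of choice set `s` and `p_s` are their
#' multinomial-logit choice probabilities under `beta`.
#'
#' @param design A `choice_design`.
#' @param beta Coefficient vector (coding-map order).
#' @return Symmetric positive semi-definite matrix.
#' @export
mnl_information_matrix <- function(design, beta) {
  cm <- coding_map(design$schema)
  p <- nrow(cm)
  if (length(beta) != p) {
    stop("beta has length ", length(beta), ", expected ", p)
  }
  M <- matrix(0, p, p, dimnames = list(cm$column, cm$column))
  for (set in design$sets) {
    X <- rbind(effects_code(design$schema, set$profiles[[1L]]),
               effects_code(design$schema, set$profiles[[2L]]))
    u <- drop(X %*% beta)
    u <- u - max(u)
    pr <- exp(u) / sum(exp(u))
    W <- diag(pr) - tcrossprod(pr)
    M <- M + t(X) %*% W %*% X
  }
  M
}

#' Bayesian D-criterion of a design
#'
#' The mean, over a sample of coefficient vectors from the design prior, of
#' the log-determinant of the design's MNL information matrix. Returns
#' `-Inf` when the information matrix is singular (condition number beyond
#' about 1e10) for any draw.
#'
#' @param design A `choice_design`.
#' @param draws Either a `prior_spec` (its seeded sample is used) or a
#'   `draws x dim` matrix of coefficient draws.
#' @return Scalar criterion value (`-Inf` sentinel when singular).
#' @export
bayesian_d_criterion <- function(design, draws) {
  if (inherits(draws, "prior_spec")) draws <- sample_prior(draws)
  draws <- as.matrix(draws)
  D <- design_diff_matrix(design)
  if (ncol(draws) != ncol(D)) {
    stop("draw matrix has ", ncol(draws), " columns, expected ", ncol(D))
  }
  cpp_bayes_logdet(D, draws)
}

# per-attribute prior-mean level scores (K x 3), used for dominance checks
prior_level_scores <- function(schema, prior_mean) {
  ids <- schema_ids(schema)
  t(vapply(ids, function(a) level_utilities(schema, prior_mean, a),
           numeric(3)))
}

# dominance for level-index rows under a K x 3 score matrix
dominated_idx <- function(i1, i2, scores) {
  d <- scores[cbind(seq_along(i1), i1)] - scores[cbind(seq_along(i2), i2)]
  (all(d >= 0) && any(d > 0)) || (all(d <= 0) && any(d < 0))
}

# Assemble a choice_design from level-index matrices (n_sets x K, values
# 1..3 indexing DCE_LEVELS) plus a balance plan.
design_from_levels <- function(schema, L1, L2, plan, n_blocks,
                               criterion_value = NA_real_, converged = NA) {
  ids <- schema_ids(schema)
  n_sets <- nrow(L1)
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    p1 <- setNames(DCE_LEVELS[L1[s, ]], ids)
    p2 <- setNames(DCE_LEVELS[L2[s, ]], ids)
    sets[[s]] <- choice_set(s, p1, p2, schema,
                            balanced_constants = plan$assignment[[s]])
  }
  blocks <- setNames(((seq_len(n_sets) - 1L) %% n_blocks) + 1L,
                     seq_len(n_sets))
  new_choice_design(schema, sets, blocks, plan$n_varying_max,
                    criterion_value, plan, converged)
}

# Random feasible starting point: planned constants at no_change, varying
# attributes uniform, redrawn until the set has a trade-off (not dominated
# under `scores`, at least one difference).
random_levels <- function(schema, plan, scores, max_redraws = 200L) {
  ids <- schema_ids(schema)
  K <- length(ids)
  n_sets <- plan$n_sets
  L1 <- matrix(2L, n_sets, K)  # no_change
  L2 <- matrix(2L, n_sets, K)
  for (s in seq_len(n_sets)) {
    varying <- which(!(ids %in% plan$assignment[[s]]))
    for (tr in seq_len(max_redraws)) {
      L1[s, varying] <- sample.int(3L, length(varying), replace = TRUE)
      L2[s, varying] <- sample.int(3L, length(varying), replace = TRUE)
      if (any(L1[s, ] != L2[s, ]) && !dominated_idx(L1[s, ], L2[s, ], scores))
        break
    }
  }
  list(L1 = L1, L2 = L2)
}

#' Generate a random feasible design sharing a balance plan
#'
#' Benchmark generator: planned constants at `no_change`, varying levels
#' uniform subject to the no-dominance and non-identical constraints. Used
#' to check that optimized designs beat random ones.
#'
#' @param schema A `dce_schema`.
#' @param plan A `balance_plan`.
#' @param prior A `prior_spec` (its mean defines the dominance ordering).
#' @param n_blocks Number of survey blocks.
#' @param seed Integer seed.
#' @return A `choice_design` (criterion not evaluated).
#' @export
random_feasible_design <- function(schema, plan, prior, n_blocks = 1L,
                                   seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  scores <- prior_level_scores(schema, prior$mean)
  lv <- random_levels(schema, plan, scores)
  design_from_levels(schema, lv$L1, lv$L2, plan, n_blocks)
}

# difference row for set s given level-index rows
diff_row <- function(i1, i2) {
  as.vector(t(EFFECTS_CODES[i1, , drop = FALSE] -
              EFFECTS_CODES[i2, , drop = FALSE]))
}

#' Optimize a Bayesian D-optimal partial-profile design
#'
#' Builds an attribute balance plan, then runs a coordinate-exchange search:
#' for every choice set, every varying attribute and each of the two
#' profiles, all three outcome levels are tried and a move is kept only on
#' strict improvement of the Bayesian D-criterion. Candidate moves that
#' would make one profile dominate the other under the prior-mean level
#' ordering are never accepted, so emitted designs contain no dominated
#' choice set. The search restarts from several random feasible designs and
#' keeps the best. Varying attributes whose levels coincide in both
#' profiles of an optimized set are recorded as incidental constants;
#' planned constants sit at `no_change` in both profiles. Survey blocks are
#' assigned round-robin over the optimized set order.
#'
#' @param schema A `dce_schema`.
#' @param prior A `prior_spec` from [build_ordered_prior()].
#' @param n_sets Number of choice sets (divisible by `n_blocks`).
#' @param n_varying_max Maximum varying attributes per set.
#' @param n_blocks Number of survey blocks.
#' @param restarts Number of random starts.
#' @param seed Integer root seed.
#' @param draws Number of prior draws for the criterion (defaults to the
#'   prior's `draws`).
#' @param max_sweeps Cap on full coordinate-exchange sweeps per start; if
#'   reached without convergence the best design found is returned with
#'   `converged = FALSE` and a warning.
#' @return A `choice_design` with `criterion_value` re-evaluated on the
#'   final design.
#' @export
optimize_design <- function(schema, prior, n_sets, n_varying_max,
                            n_blocks = 1L, restarts = 4L, seed = 1L,
                            draws = NULL, max_sweeps = 50L) {
  if (n_sets %% n_blocks != 0L) {
    stop("n_sets must be divisible by n_blocks")
  }
  plan <- plan_attribute_balance(schema, n_sets, n_varying_max,
                                 seed = derive_seed(seed, 0L))
  B <- sample_prior(prior, draws %||% prior$draws)
  scores <- prior_level_scores(schema, prior$mean)
  ids <- schema_ids(schema)
  K <- length(ids)
  best <- NULL
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    res <- exchange_one_start(schema, plan, B, scores, max_sweeps)
    if (is.null(res)) next
    if (is.null(best) || res$crit > best$crit) best <- res
  }
  if (is.null(best)) {
    stop("design optimization failed: information matrix singular for ",
         "every start (design too small for the coding dimension?)")
  }
  if (!best$converged) {
    warning("coordinate exchange hit the sweep cap; returning best design found")
  }
  design <- design_from_levels(schema, best$L1, best$L2, plan, n_blocks,
                               converged = best$converged)
  design$criterion_value <- bayesian_d_criterion(design, B)
  design
}

# One coordinate-exchange run from a fresh random start. Returns NULL when
# no start with a non-singular information matrix is found. Neighborhood:
# for small sets (at most two varying attributes) all joint level
# assignments of the two partial profiles are tried at once, which escapes
# local optima that attribute-wise moves cannot; otherwise each varying
# attribute's nine level pairs are tried in turn. Moves are kept only on
# strict criterion improvement (incumbent retained on ties, preventing
# cycling); convergence is a full sweep without an accepted move.
exchange_one_start <- function(schema, plan, B, scores, max_sweeps) {
  ids <- schema_ids(schema)
  K <- length(ids)
  n_sets <- plan$n_sets
  lv <- state <- NULL
  for (tr in 1:20) {
    lv <- random_levels(schema, plan, scores)
    D <- t(vapply(seq_len(n_sets),
                  function(s) diff_row(lv$L1[s, ], lv$L2[s, ]),
                  numeric(2L * K)))
    state <- cpp_exchange_init(D, B)
    if (state$ok) break
    state <- NULL
  }
  if (is.null(state)) return(NULL)
  L1 <- lv$L1; L2 <- lv$L2
  crit <- mean(state$logdet)
  varying <- lapply(seq_len(n_sets),
                    function(s) which(!(ids %in% plan$assignment[[s]])))
  # evaluate all candidate (i1, i2) varying-level rows for set s over the
  # attribute positions `cols`; accept the best strictly improving move
  try_moves <- function(s, cols, cand1, cand2) {
    d_old <- diff_row(L1[s, ], L2[s, ])
    best_gain <- crit + 1e-9
    best_move <- NULL
    for (cb in seq_len(nrow(cand1))) {
      i1 <- L1[s, ]; i2 <- L2[s, ]
      i1[cols] <- cand1[cb, ]
      i2[cols] <- cand2[cb, ]
      if (all(i1 == L1[s, ]) && all(i2 == L2[s, ])) next
      if (all(i1 == i2)) next
      if (dominated_idx(i1, i2, scores)) next
      cand_crit <- cpp_candidate_crit(state$Minv, state$logdet,
                                      dim(state$Minv), B, d_old,
                                      diff_row(i1, i2))
      if (is.finite(cand_crit) && cand_crit > best_gain) {
        best_gain <- cand_crit
        best_move <- list(i1 = i1, i2 = i2)
      }
    }
    if (is.null(best_move)) return(FALSE)
    cpp_accept_update(state$Minv, state$logdet, dim(state$Minv), B,
                      d_old, diff_row(best_move$i1, best_move$i2))
    L1[s, ] <<- best_move$i1
    L2[s, ] <<- best_move$i2
    crit <<- mean(state$logdet)
    TRUE
  }
  pair_combos <- as.matrix(expand.grid(l1 = 1:3, l2 = 1:3))
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (s in seq_len(n_sets)) {
      v <- varying[[s]]
      if (length(v) <= 2L) {
        grid <- as.matrix(expand.grid(rep(list(1:3), 2L * length(v))))
        cand1 <- grid[, seq_along(v), drop = FALSE]
        cand2 <- grid[, length(v) + seq_along(v), drop = FALSE]
        if (try_moves(s, v, cand1, cand2)) improved <- TRUE
      } else {
        for (a in v) {
          if (try_moves(s, a, pair_combos[, 1L, drop = FALSE],
                        pair_combos[, 2L, drop = FALSE])) improved <- TRUE
        }
      }
    }
    # refresh the rank-one-updated state to curb numerical drift
    D <- t(vapply(seq_len(n_sets),
                  function(s) diff_row(L1[s, ], L2[s, ]),
                  numeric(2L * K)))
    state <- cpp_exchange_init(D, B)
    if (!state$ok) return(NULL)
    crit <- mean(state$logdet)
    if (!improved) { converged <- TRUE; break }
  }
  list(L1 = L1, L2 = L2, crit = crit, converged = converged)
}

# ---- serialization ---------------------------------------------------------

#' Write / read a choice design as CSV
#'
#' One row per (choice set, alternative): `set_id`, `alt`, `block`, one
#' column per attribute holding the short level labels `pos`/`nc`/`neg`,
#' and a `constants` column marking planned (`*`) and incidental (`SS`)
#' constant attributes as `id=*` / `id=SS` pairs separated by `;`.
#'
#' @param design A `choice_design`.
#' @param path CSV file path.
#' @param schema Schema used to validate levels on read.
#' @return `write_design_csv` invisibly returns `path`; `read_design_csv`
#'   returns a `choice_design` (criterion value not re-evaluated).
#' @export
write_design_csv <- function(design, path) {
  ids <- schema_ids(design$schema)
  rows <- lapply(design$sets, function(set) {
    marks <- c(setNames(rep("*", length(set$balanced_constant_ids)),
                        set$balanced_constant_ids),
               setNames(rep("SS", length(set$incidental_constant_ids)),
                        set$incidental_constant_ids))
    const <- paste(paste0(names(marks), "=", marks), collapse = ";")
    do.call(rbind, lapply(1:2, function(j) {
      lv <- SHORT_LEVELS[set$profiles[[j]][ids]]
      data.frame(set_id = set$id, alt = j,
                 block = unname(design$blocks[[as.character(set$id)]]),
                 as.list(setNames(lv, ids)), constants = const,
                 stringsAsFactors = FALSE)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, schema) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- schema_ids(schema)
  missing_cols <- setdiff(c("set_id", "alt", "block", ids), names(df))
  if (length(missing_cols)) {
    stop("design file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sets <- list()
  blocks <- integer()
  n_vary <- 0L
  for (sid in unique(df$set_id)) {
    sub <- df[df$set_id == sid, ]
    sub <- sub[order(sub$alt), ]
    if (nrow(sub) != 2L) stop("choice set ", sid, " does not have 2 alternatives")
    p1 <- setNames(normalize_level(unlist(sub[1L, ids])), ids)
    p2 <- setNames(normalize_level(unlist(sub[2L, ids])), ids)
    bal <- character()
    if ("constants" %in% names(df) && nzchar(sub$constants[1L])) {
      toks <- strsplit(sub$constants[1L], ";", fixed = TRUE)[[1L]]
      kv <- strsplit(toks, "=", fixed = TRUE)
      bal <- vapply(kv[vapply(kv, function(x) x[2L] == "*", TRUE)],
                    `[[`, "", 1L)
    }
    set <- choice_set(sid, p1, p2, schema, balanced_constants = bal)
    sets[[length(sets) + 1L]] <- set
    blocks[[as.character(sid)]] <- as.integer(sub$block[1L])
    n_vary <- max(n_vary, n_varying(set))
  }
  new_choice_design(schema, sets, blocks, n_vary)
}

#' Structural report of a design
#'
#' Summarizes the design's Bayesian D-criterion, per-attribute constancy
#' counts (planned and incidental), pairwise co-constancy counts of planned
#' constants, and a per-set dominance check under a level ordering.
#'
#' @param design A `choice_design`.
#' @param ordering Level ordering for the dominance log (best first).
#' @param path Optional path; when given, the report is written as JSON.
#' @return A list (invisibly when `path` is given).
#' @export
design_report <- function(design, ordering = DCE_LEVELS, path = NULL) {
  ids <- schema_ids(design$schema)
  planned <- sapply(ids, function(a)
    sum(vapply(design$sets, function(s) a %in% s$balanced_constant_ids, TRUE)))
  incidental <- sapply(ids, function(a)
    sum(vapply(design$sets, function(s) a %in% s$incidental_constant_ids, TRUE)))
  dom <- vapply(design$sets, dominance_check, TRUE, ordering = ordering)
  pair <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in design$sets) {
    b <- s$balanced_constant_ids
    pair[b, b] <- pair[b, b] + 1L
    diag(pair) <- 0L
  }
  report <- list(
    n_sets = length(design$sets),
    n_blocks = length(unique(design$blocks)),
    criterion_value = design$criterion_value,
    planned_constancy = as.list(planned),
    incidental_constancy = as.list(incidental),
    pair_co_constancy = pair,
    n_varying = vapply(design$sets, n_varying, 1L),
    dominated_sets = which(dom)
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
    return(invisible(report))
  }
  report
}
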