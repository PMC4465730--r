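#' Multivariate normal prior over choice-model coefficients
#'
#' The design optimizer averages the D-criterion over a sample from a
#' multivariate normal belief about the utility coefficients. The prior
#' mean encodes two a-priori assumptions: within every attribute a positive
#' outcome is preferred to no change, which is preferred to a negative
#' outcome; and, by loss aversion, avoiding a negative outcome weighs more
#' than attaining a positive one. Attributes ranked less important a priori
#' get geometrically smaller mean utilities.
#'
#' For an attribute with importance rank `r` the prior-mean level utilities
#' are `(+g_r, 0, -loss_aversion * g_r)` with
#' `g_r = base_gap * rank_decay^(r - 1)`, mapped into effects-coding space.
#'
#' @param schema A [build_schema()] schema.
#' @param base_gap Mean utility gap (utility units) between a positive and a
#'   no-change outcome for the top-ranked attribute. Must be > 0.
#' @param loss_aversion Multiplier (>= 1) applied to the negative-outcome
#'   utility magnitude.
#' @param rank_decay Geometric decay in (0, 1] of the gap across ranks.
#' @param sd Prior standard deviation per coefficient (diagonal covariance)
#'   unless `covariance` is supplied.
#' @param draws Monte-Carlo sample size used by [sample_prior()].
#' @param seed Integer seed making prior draws reproducible.
#' @param covariance Optional full covariance matrix (must be symmetric
#'   positive definite and match the coding dimension).
#' @return An object of class `prior_spec`: list with `mean`, `covariance`,
#'   `draws`, `seed`.
#' @export
build_ordered_prior <- function(schema, base_gap = 1, loss_aversion = 1.5,
                                rank_decay = 0.9, sd = 0.5, draws = 512L,
                                seed = 1L, covariance = NULL) {
  stopifnot(base_gap > 0, sd > 0, loss_aversion >= 1,
            rank_decay > 0, rank_decay <= 1, draws >= 1)
  ranks <- schema$attributes$rank
  gap <- base_gap * rank_decay^(ranks - 1)
  # level utilities (pos, nc, neg) must sum to zero for effects coding; the
  # raw target (+g, 0, -L g) is centered before coding.
  util <- cbind(gap, 0, -loss_aversion * gap)
  util <- util - rowMeans(util)
  mean_beta <- utilities_to_beta(schema, util)
  names(mean_beta) <- coding_map(schema)$column
  p <- length(mean_beta)
  if (is.null(covariance)) {
    covariance <- diag(sd^2, p)
  } else {
    covariance <- as.matrix(covariance)
    if (!all(dim(covariance) == p)) {
      stop("covariance dimension ", nrow(covariance),
           " does not match coding dimension ", p)
    }
    if (max(abs(covariance - t(covariance))) > 1e-8) {
      stop("covariance must be symmetric")
    }
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev))) {
      stop("covariance is not positive (semi-)definite")
    }
  }
  dimnames(covariance) <- list(names(mean_beta), names(mean_beta))
  structure(list(mean = mean_beta, covariance = covariance,
                 draws = as.integer(draws), seed = as.integer(seed)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("MVN prior over", length(x$mean), "coefficients;",
      x$draws, "draws, seed", x$seed, "\n")
  invisible(x)
}

#' Draw a Monte-Carlo sample from a coefficient prior
#'
#' Reproducible given the prior's seed: the same `prior_spec` always yields
#' the same draw matrix.
#'
#' @param prior A `prior_spec`.
#' @param draws Number of draws (defaults to `prior$draws`).
#' @return A `draws x dim` matrix of coefficient vectors.
#' @export
sample_prior <- function(prior, draws = prior$draws) {
  stopifnot(draws >= 1)
  p <- length(prior$mean)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(prior$seed)
  z <- matrix(rnorm(draws * p), draws, p)
  # matrix square root via eigen decomposition (tolerates PSD covariance)
  ed <- eigen(prior$covariance, symmetric = TRUE)
  rt <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  out <- sweep(z %*% rt, 2L, prior$mean, "+")
  colnames(out) <- names(prior$mean)
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Write / read a prior specification as JSON
#'
#' @param prior A `prior_spec`.
#' @param path File path.
#' @return `prior_to_json` invisibly returns `path`; `prior_from_json`
#'   returns the reconstructed `prior_spec`.
#' @export
prior_to_json <- function(prior, path) {
  obj <- list(mean = as.numeric(prior$mean),
              labels = names(prior$mean),
              covariance = unname(as.matrix(prior$covariance)),
              draws = prior$draws, seed = prior$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname prior_to_json
#' @export
prior_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mean <- setNames(as.numeric(obj$mean), obj$labels)
  cov <- as.matrix(obj$covariance)
  dimnames(cov) <- list(obj$labels, obj$labels)
  structure(list(mean = mean, covariance = cov,
                 draws = as.integer(obj$draws), seed = as.integer(obj$seed)),
            class = "prior_spec")
}
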