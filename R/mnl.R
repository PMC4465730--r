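#' Specify a choice model: main effects plus subgroup interactions
#'
#' The utility of an alternative is the sum of the effects-coded marginal
#' utilities of every attribute (main effects) plus interaction
#' contributions in which a respondent covariate multiplies an attribute's
#' coded columns. Because the two alternatives of a forced pair are
#' unlabeled, respondent-level main effects cancel; covariates therefore
#' enter only through interactions with attribute codes. Covariates are
#' centered at their respondent-table mean (continuous ones also scaled to
#' SD 1) before interacting, so the fitted main effects are
#' population-average marginal utilities and subgroup offsets are
#' deviations from them.
#'
#' @param schema A `dce_schema`.
#' @param interactions Data.frame with columns `covariate` and `attribute`
#'   (or a list of 2-element character vectors). Duplicated terms are
#'   dropped.
#' @param adjust Character vector of respondent covariates to adjust for;
#'   each is expanded to interactions with every attribute.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(schema, interactions = NULL, adjust = NULL) {
  terms <- data.frame(covariate = character(), attribute = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(interactions)) {
    if (is.list(interactions) && !is.data.frame(interactions)) {
      interactions <- do.call(rbind, lapply(interactions, function(x)
        data.frame(covariate = x[[1L]], attribute = x[[2L]],
                   stringsAsFactors = FALSE)))
    }
    terms <- rbind(terms, interactions[, c("covariate", "attribute")])
  }
  if (!is.null(adjust)) {
    terms <- rbind(terms, expand.grid(covariate = adjust,
                                      attribute = schema_ids(schema),
                                      stringsAsFactors = FALSE))
  }
  terms <- unique(terms)
  bad <- setdiff(terms$attribute, schema_ids(schema))
  if (length(bad)) stop("unknown attribute(s) in interactions: ",
                        paste(bad, collapse = ", "))
  structure(list(schema = schema, terms = terms), class = "model_spec")
}

#' Model specification matching a simulation truth
#'
#' Convenience: one interaction term per interaction offset of the truth,
#' so the fitted model is correctly specified for data simulated from it.
#'
#' @param schema A `dce_schema`.
#' @param truth A `truth_spec`.
#' @return A `model_spec`.
#' @export
spec_from_truth <- function(schema, truth) {
  if (length(truth$interactions) == 0L) return(model_spec(schema))
  model_spec(schema, interactions = do.call(rbind, lapply(
    truth$interactions, function(tr)
      data.frame(covariate = tr$covariate, attribute = tr$attribute,
                 stringsAsFactors = FALSE))))
}

# Assemble the per-choice-set difference design matrix. Returns list with
# X (n_sets x P), y (1 if alternative 1 chosen), labels, the number of main
# columns, and the covariate centering/scaling constants.
model_matrix_mnl <- function(dataset, spec) {
  schema <- spec$schema
  ids <- schema_ids(schema)
  obs <- dataset$observations
  ord <- order(obs$respondent_id, obs$set_id, obs$alt)
  obs <- obs[ord, ]
  n2 <- nrow(obs)
  if (n2 %% 2L != 0L) stop("observations do not pair up")
  i1 <- seq(1L, n2, by = 2L)
  i2 <- i1 + 1L
  if (any(obs$respondent_id[i1] != obs$respondent_id[i2]) ||
      any(obs$set_id[i1] != obs$set_id[i2])) {
    stop("each answered choice set needs exactly two alternatives")
  }
  chosen <- obs$chosen[i1] + obs$chosen[i2]
  if (any(chosen != 1L)) {
    stop("each answered choice set must have exactly one chosen alternative")
  }
  Xall <- effects_code_matrix(schema, obs[, ids, drop = FALSE])
  d_main <- Xall[i1, , drop = FALSE] - Xall[i2, , drop = FALSE]
  resp <- dataset$respondents
  ridx <- match(obs$respondent_id[i1], resp$id)
  blocks <- list(d_main)
  labels <- colnames(d_main)
  transforms <- data.frame(covariate = character(), center = numeric(),
                           scale = numeric(), stringsAsFactors = FALSE)
  if (nrow(spec$terms) > 0L) {
    for (t in seq_len(nrow(spec$terms))) {
      cv <- spec$terms$covariate[t]
      at <- spec$terms$attribute[t]
      if (!cv %in% names(resp)) {
        stop("model covariate '", cv, "' absent from respondent table")
      }
      z <- resp[[cv]]
      # Covariates are centered (continuous ones also scaled to SD 1), so
      # the main-effect columns estimate population-average utilities and
      # interaction columns are near-orthogonal to them.
      ctr <- mean(z)
      sc <- if (all(z %in% c(0, 1))) 1 else stats::sd(z)
      if (!cv %in% transforms$covariate) {
        transforms <- rbind(transforms, data.frame(
          covariate = cv, center = ctr, scale = sc,
          stringsAsFactors = FALSE))
      }
      zt <- (z - ctr) / sc
      k <- match(at, ids)
      cols <- c(2L * k - 1L, 2L * k)
      blocks[[length(blocks) + 1L]] <- zt[ridx] * d_main[, cols, drop = FALSE]
      labels <- c(labels, paste0(cv, ":", colnames(d_main)[cols]))
    }
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- labels
  list(X = X, y = obs$chosen[i1], labels = labels,
       n_main = ncol(d_main), transforms = transforms)
}

#' Log-likelihood of a choice model
#'
#' Sum over answered choice sets of the chosen alternative's utility minus
#' the log-sum-exp of both utilities, evaluated overflow-safely.
#'
#' @param dataset A `choice_dataset`.
#' @param spec A `model_spec`.
#' @param beta Coefficient vector matching the spec's dimension.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, spec, beta) {
  mm <- model_matrix_mnl(dataset, spec)
  if (length(beta) != ncol(mm$X)) {
    stop("beta has length ", length(beta), ", expected ", ncol(mm$X))
  }
  eta <- drop(mm$X %*% beta)
  q <- ifelse(mm$y == 1L, 1, -1)
  # log P(chosen) = log plogis(q * eta)
  sum(plogis(q * eta, log.p = TRUE))
}

negll_grad <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  -drop(crossprod(X, y - p))
}

negll_fun <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  q <- ifelse(y == 1L, 1, -1)
  -sum(plogis(q * eta, log.p = TRUE))
}

#' Fit the choice model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization started from zero coefficients,
#' followed by Newton steps until the gradient max-norm falls below 1e-6.
#' The coefficient covariance is the inverse observed information at the
#' optimum. The fit is deterministic given the data.
#'
#' @param dataset A `choice_dataset`.
#' @param spec A `model_spec`.
#' @param max_newton Cap on Newton polish iterations.
#' @return An object of class `mnl_fit`: `coefficients`, `vcov`,
#'   `log_likelihood`, `n_choice_sets`, `converged`, `gradient_norm`,
#'   `spec`.
#' @export
fit_mnl <- function(dataset, spec, max_newton = 50L) {
  mm <- model_matrix_mnl(dataset, spec)
  X <- mm$X
  y <- mm$y
  degenerate <- colSums(abs(X)) == 0
  if (any(degenerate)) {
    stop("non-identifiable coefficient column(s) (no variation within any ",
         "choice set): ", paste(mm$labels[degenerate], collapse = ", "))
  }
  P <- ncol(X)
  opt <- optim(rep(0, P), fn = negll_fun, gr = negll_grad, X = X, y = y,
               method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-14))
  beta <- opt$par
  grad <- negll_grad(beta, X, y)
  newton_ok <- TRUE
  for (it in seq_len(max_newton)) {
    if (max(abs(grad)) < 1e-6) break
    p <- plogis(drop(X %*% beta))
    w <- p * (1 - p)
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, -grad), error = function(e) NULL)
    if (is.null(step)) { newton_ok <- FALSE; break }
    # backtracking on the negative log-likelihood
    f0 <- negll_fun(beta, X, y)
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (negll_fun(cand, X, y) <= f0 + 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    grad <- negll_grad(beta, X, y)
  }
  converged <- newton_ok && max(abs(grad)) < 1e-6
  p <- plogis(drop(X %*% beta))
  w <- p * (1 - p)
  H <- crossprod(X, X * w)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc)) {
    warning("observed information singular; using pseudo-inverse covariance")
    ed <- eigen(H, symmetric = TRUE)
    pos <- ed$values > max(ed$values) * 1e-12
    vc <- ed$vectors[, pos, drop = FALSE] %*%
      ((1 / ed$values[pos]) * t(ed$vectors[, pos, drop = FALSE]))
  }
  dimnames(vc) <- list(mm$labels, mm$labels)
  if (!converged) {
    warning("maximum-likelihood fit did not reach gradient tolerance")
  }
  structure(list(coefficients = setNames(beta, mm$labels), vcov = vc,
                 log_likelihood = -negll_fun(beta, X, y),
                 n_choice_sets = length(y), converged = converged,
                 gradient_norm = max(abs(grad)), spec = spec,
                 covariate_transforms = mm$transforms),
            class = "mnl_fit")
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat("Conditional (MNL) logit fit:", length(x$coefficients),
      "coefficients on", x$n_choice_sets, "choice sets\n")
  cat("log-likelihood:", format(x$log_likelihood, digits = 8),
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Likelihood-ratio test of one attribute's overall significance
#'
#' Refits the model with the attribute's main-effect columns removed while
#' keeping all interaction terms, and compares twice the log-likelihood
#' difference to a chi-square distribution with as many degrees of freedom
#' as removed columns (2 for a three-level attribute).
#'
#' @param dataset A `choice_dataset`.
#' @param spec A `model_spec`.
#' @param fit The full-model `mnl_fit`.
#' @param attribute_id Attribute to test.
#' @return List with `statistic`, `df`, `p_value` and `log_p` (natural-log
#'   p-value, exact even when `p_value` underflows).
#' @export
lr_test_attribute <- function(dataset, spec, fit, attribute_id) {
  schema <- spec$schema
  ids <- schema_ids(schema)
  k <- match(attribute_id, ids)
  if (is.na(k)) stop("unknown attribute id '", attribute_id, "'")
  mm <- model_matrix_mnl(dataset, spec)
  drop_cols <- c(2L * k - 1L, 2L * k)
  keep <- setdiff(seq_len(ncol(mm$X)), drop_cols)
  Xr <- mm$X[, keep, drop = FALSE]
  opt <- optim(rep(0, ncol(Xr)), fn = negll_fun, gr = negll_grad,
               X = Xr, y = mm$y, method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-14))
  beta <- opt$par
  grad <- negll_grad(beta, Xr, mm$y)
  for (it in 1:50) {
    if (max(abs(grad)) < 1e-6) break
    p <- plogis(drop(Xr %*% beta))
    H <- crossprod(Xr, Xr * (p * (1 - p)))
    step <- tryCatch(solve(H, -grad), error = function(e)
      stop("reduced model did not converge for attribute '",
           attribute_id, "'"))
    beta <- beta + step
    grad <- negll_grad(beta, Xr, mm$y)
  }
  ll_reduced <- -negll_fun(beta, Xr, mm$y)
  stat <- max(0, 2 * (fit$log_likelihood - ll_reduced))
  df <- length(drop_cols)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       log_p = pchisq(stat, df, lower.tail = FALSE, log.p = TRUE))
}

#' Likelihood-ratio table over all attributes
#'
#' @param dataset A `choice_dataset`.
#' @param spec A `model_spec`.
#' @param fit The full-model `mnl_fit`.
#' @return Data.frame with one row per attribute: `attribute`, `statistic`,
#'   `df`, `p_value`, `log_p`.
#' @export
lr_table <- function(dataset, spec, fit) {
  rows <- lapply(schema_ids(spec$schema), function(a) {
    tst <- lr_test_attribute(dataset, spec, fit, a)
    data.frame(attribute = a, statistic = tst$statistic, df = tst$df,
               p_value = tst$p_value, log_p = tst$log_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a fit report as JSON
#'
#' @param fit An `mnl_fit`.
#' @param path File path.
#' @param lr Optional LR table from [lr_table()].
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path, lr = NULL) {
  se <- sqrt(pmax(diag(fit$vcov), 0))
  obj <- list(
    coefficients = as.list(setNames(as.numeric(fit$coefficients),
                                    names(fit$coefficients))),
    standard_errors = as.list(setNames(as.numeric(se),
                                       names(fit$coefficients))),
    log_likelihood = fit$log_likelihood,
    n_choice_sets = fit$n_choice_sets,
    converged = fit$converged
  )
  if (!is.null(lr)) obj$lr_table <- lr
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
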