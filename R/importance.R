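#' Relative attribute importance from likelihood-ratio tests
#'
#' Raw importance of an attribute is `-log(p)` of its LR test; scaled
#' importance rescales so that the most significant attribute scores
#' exactly 100: `100 * log(p_attr) / log(p_min)`. The ratio of logarithms
#' makes the scale invariant to the logarithm base. P-values below the
#' numeric floor (1e-300) are clamped and flagged; when the exact
#' natural-log p-value is available in the input (`log_p` column) it is
#' used for the scaling, so attributes whose p-values underflow retain
#' their exact ordering.
#'
#' @param lr LR table: data.frame with columns `attribute`, `p_value` and
#'   optionally `log_p` (natural log).
#' @param floor Smallest representable p-value before clamping.
#' @return Data.frame of class `importance_table`: `attribute`, `p_value`,
#'   `raw_importance` (`-log10 p`), `scaled_importance` in [0, 100],
#'   `clamped`.
#' @export
importance_table <- function(lr, floor = 1e-300) {
  stopifnot(all(c("attribute", "p_value") %in% names(lr)))
  p <- lr$p_value
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in (0, 1]")
  clamped <- p < floor
  p_use <- pmax(p, floor)
  log_p <- if ("log_p" %in% names(lr)) lr$log_p else log(p_use)
  log_p <- pmin(log_p, 0)
  lp_min <- min(log_p)
  scaled <- if (lp_min == 0) rep(100, length(log_p)) else 100 * log_p / lp_min
  out <- data.frame(attribute = lr$attribute, p_value = p_use,
                    raw_importance = -log_p / log(10),
                    scaled_importance = scaled, clamped = clamped,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$scaled_importance), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Reference-standardized marginal utilities of a fitted model
#'
#' Marginal utilities have no absolute scale, so every reported level
#' utility is divided by the absolute value of the pooled main-effect
#' utility of the schema's reference (attribute, level) pair; the reference
#' itself maps to -1. Subgroup contexts add the fitted interaction
#' contributions before standardizing by the same pooled denominator, which
#' keeps utilities comparable across subgroups.
#'
#' @param fit An `mnl_fit`.
#' @param schema The schema (defaults to the fit's).
#' @param contexts Named list of contexts; each context is a named list /
#'   vector of raw covariate values (e.g. `list(physician = 1)`); values
#'   are transformed with the fit's centering/scaling constants, and
#'   covariates left unspecified sit at their population mean. The default
#'   single context `pooled` is therefore the main-effects-only
#'   (population-average) context.
#' @return Data.frame of class `standardized_utilities`: `context`,
#'   `attribute`, `level`, `utility` (standardized). The attribute
#'   `reference_value` carries the raw pooled reference utility.
#' @export
standardize_utilities <- function(fit, schema = fit$spec$schema,
                                  contexts = list(pooled = list())) {
  ids <- schema_ids(schema)
  n_main <- 2L * length(ids)
  beta_main <- fit$coefficients[seq_len(n_main)]
  ref_raw <- level_utilities(schema, beta_main,
                             schema$reference_attribute)[[schema$reference_level]]
  if (abs(ref_raw) < 1e-8) {
    stop("reference level utility is numerically zero; cannot standardize")
  }
  terms <- fit$spec$terms
  rows <- list()
  for (cn in names(contexts)) {
    ctx <- contexts[[cn]]
    beta_ctx <- beta_main
    if (nrow(terms) > 0L) {
      tf <- fit$covariate_transforms
      for (t in seq_len(nrow(terms))) {
        cv <- terms$covariate[t]
        z <- ctx[[cv]]
        if (is.null(z)) next  # unspecified -> population mean -> no offset
        i <- match(cv, tf$covariate)
        zt <- (z - tf$center[i]) / tf$scale[i]
        if (zt == 0) next
        k <- match(terms$attribute[t], ids)
        cols <- c(2L * k - 1L, 2L * k)
        lab <- paste0(cv, ":", names(beta_main)[cols])
        beta_ctx[cols] <- beta_ctx[cols] + zt * fit$coefficients[lab]
      }
    }
    for (a in ids) {
      lu <- level_utilities(schema, beta_ctx, a)
      rows[[length(rows) + 1L]] <- data.frame(
        context = cn, attribute = a, level = names(lu),
        utility = as.numeric(lu) / abs(ref_raw), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_value") <- ref_raw
  attr(out, "reference") <- c(schema$reference_attribute,
                              schema$reference_level)
  class(out) <- c("standardized_utilities", "data.frame")
  out
}

#' Proportional excess of one standardized utility over another
#'
#' `a / b - 1`: how many times more a reform outcome affects one subgroup's
#' choices than another's. Reports round the value to 2 decimals.
#'
#' @param a,b Standardized utilities (same sign convention); `b` must be
#'   nonzero.
#' @return The raw (unrounded) excess.
#' @export
#' @examples
#' round_half_up(ratio_excess(1.13, 0.87), 2)  # 0.30
ratio_excess <- function(a, b) {
  if (b == 0) stop("ratio_excess is undefined for a zero denominator")
  a / b - 1
}

#' Round half away from zero
#'
#' Table-style display rounding (0.125 -> 0.13), unlike base R's
#' round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Bar chart of attribute importances
#'
#' @param imp An `importance_table`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_importance <- function(imp) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_importance requires the ggplot2 package")
  }
  imp$attribute <- factor(imp$attribute, levels = rev(imp$attribute))
  ggplot2::ggplot(imp, ggplot2::aes(x = scaled_importance, y = attribute)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Relative importance (most important = 100)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of standardized marginal utilities by outcome level
#'
#' @param std A `standardized_utilities` table.
#' @param context Which context to plot.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_marginal_utilities <- function(std, context = "pooled") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_marginal_utilities requires the ggplot2 package")
  }
  df <- std[std$context == context, ]
  df$level <- factor(df$level, levels = DCE_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = utility, y = attribute,
                                   fill = level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Standardized marginal utility (reference = -1)",
                  y = NULL, fill = "Outcome") +
    ggplot2::theme_minimal()
}
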