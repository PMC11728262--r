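## Ordinary least-squares analyses for sensitivity, decision bias and
## metacognitive bias.

#' Ordinary least-squares fit of one interoceptive measure
#'
#' Fits \code{y} on a global intercept plus the design columns by OLS (via
#' \code{\link[stats]{lm}}), returning the coefficient table with two-tailed
#' t-test p-values.
#'
#' @param y numeric response vector, aligned with the design rows.
#' @param design an \code{\link{build_design}} object, or a plain numeric
#'   matrix of regressors (no intercept column).
#' @param model_tag label stored with the result.
#' @return object of class \code{fdt_glm}: list with \code{coefficients}
#'   (data.frame: term, estimate, se, t, p), \code{n_used},
#'   \code{df_residual}, \code{model_tag}, and the underlying \code{lm} fit.
#' @export
fit_ols <- function(y, design, model_tag = "base") {
  X <- if (inherits(design, "fdt_design")) design$X else as.matrix(design)
  if (length(y) != nrow(X))
    stop("length(y) must match the number of design rows", call. = FALSE)
  ok <- is.finite(y)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  .check_full_rank(X)
  if (length(y) <= ncol(X) + 1L)
    stop("too few observations for the design", call. = FALSE)
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  terms[terms == "(Intercept)"] <- "intercept"
  terms <- gsub("^`|`$", "", terms)
  structure(list(
    coefficients = data.frame(term = terms, estimate = sm[, 1],
                              se = sm[, 2], t = sm[, 3], p = sm[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    n_used = length(y),
    df_residual = fit$df.residual,
    model_tag = model_tag,
    fit = fit
  ), class = "fdt_glm")
}

#' @export
print.fdt_glm <- function(x, digits = 4, ...) {
  cat(sprintf("OLS model [%s]: n = %d, residual df = %d\n",
              x$model_tag, x$n_used, x$df_residual))
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fdt_glm <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' The five-model OLS suite for one measure and one score
#'
#' Fits the analysis plan used for interoceptive sensitivity, decision bias
#' and metacognitive bias: the base model (score + site dummies), the
#' gender-interaction model, the mathematically equivalent
#' gender-specific-slope model, and the two site-collapsed sensitivity
#' variants.
#'
#' @param measures an \code{\link{fdt_measures}} object (or data.frame with
#'   \code{subject_id} and the measure column).
#' @param covariates subject covariate table.
#' @param measure name of the measure column (e.g. \code{"metacog_bias"}).
#' @param score name of the score column (e.g. \code{"stai_state"}).
#' @return object of class \code{fdt_glm_suite}: named list of
#'   \code{fdt_glm} fits (\code{base}, \code{gender}, \code{gender_slopes},
#'   \code{sensitivity_base}, \code{sensitivity_gender}) plus derived
#'   per-gender slope estimates from the interaction fit.
#' @export
run_measure_suite <- function(measures, covariates, measure, score) {
  if (!measure %in% names(measures))
    stop("measure column '", measure, "' not found", call. = FALSE)
  if (!score %in% names(covariates))
    stop("score column '", score, "' not found", call. = FALSE)
  specs <- list(
    base = list(type = "base", site = TRUE),
    gender = list(type = "gender", site = TRUE),
    gender_slopes = list(type = "gender_slopes", site = TRUE),
    sensitivity_base = list(type = "base", site = FALSE),
    sensitivity_gender = list(type = "gender", site = FALSE))
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  for (tag in names(specs)) {
    des <- suppressWarnings(
      build_design(covariates, score, type = specs[[tag]]$type,
                   include_site = specs[[tag]]$site))
    y <- measures[[measure]][match(des$subject_id, measures$subject_id)]
    fits[[tag]] <- fit_ols(y, des, model_tag = tag)
  }
  cf <- coef(fits$gender)
  structure(c(fits, list(
    measure = measure, score = score,
    slope_men = unname(cf["score_z"]),
    slope_women = unname(cf["score_z"] + cf["score_z_x_gender"])
  )), class = "fdt_glm_suite")
}

#' @export
print.fdt_glm_suite <- function(x, ...) {
  cat(sprintf("OLS suite: %s ~ %s\n", x$measure, x$score))
  for (tag in c("base", "gender", "gender_slopes",
                "sensitivity_base", "sensitivity_gender")) {
    cat("\n"); print(x[[tag]])
  }
  cat(sprintf("\nPer-gender slopes (interaction fit): men %.4f, women %.4f\n",
              x$slope_men, x$slope_women))
  invisible(x)
}
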