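## Regression design matrices shared by the OLS and hierarchical analyses.

#' Build a regression design for one psychological score
#'
#' Constructs the named regressor columns used both by the OLS analyses and
#' by the hierarchical logMratio regression. The score is z-scored over the
#' included (complete-case) subjects, before any gender split, so both
#' genders share one scale. Gender is coded 0 = man, 1 = woman. Study site
#' enters as reference-cell dummies with the largest site as reference. The
#' intercept is not a column: the OLS fitter adds one, and the hierarchical
#' model absorbs it into the population mean.
#'
#' Three parameterizations are available:
#' \describe{
#'   \item{base}{score only (+ sites).}
#'   \item{gender}{score, gender, and their interaction (+ sites).}
#'   \item{gender_slopes}{gender plus separate per-gender score columns
#'     (+ sites); spans the same space as \code{gender}, and the
#'     women-specific slope equals slope + interaction of that design.}
#' }
#'
#' @param covariates data.frame with \code{subject_id}, \code{gender},
#'   \code{site} and the score column.
#' @param score name of the score column (e.g. \code{"stai_state"}).
#' @param type one of \code{"base"}, \code{"gender"}, \code{"gender_slopes"}.
#' @param include_site include site dummies (drop for the site-collapsed
#'   sensitivity analysis).
#' @return object of class \code{fdt_design}: list with \code{X} (numeric
#'   matrix, named columns, no intercept), \code{subject_id},
#'   \code{dropped} (ids removed by listwise deletion), \code{score},
#'   \code{type}, \code{include_site}.
#' @export
build_design <- function(covariates, score,
                         type = c("base", "gender", "gender_slopes"),
                         include_site = TRUE) {
  type <- match.arg(type)
  if (!score %in% names(covariates))
    stop("score column '", score, "' not found", call. = FALSE)
  keep <- complete.cases(covariates[, c("gender", score)])
  dropped <- covariates$subject_id[!keep]
  if (length(dropped))
    warning(length(dropped), " subject(s) dropped for missing '",
            score, "' or gender", call. = FALSE)
  cv <- covariates[keep, , drop = FALSE]
  z <- as.numeric(scale(cv[[score]]))
  g <- as.numeric(cv$gender)
  cols <- switch(type,
    base = list(score_z = z),
    gender = list(score_z = z, gender = g, score_z_x_gender = z * g),
    gender_slopes = list(gender = g, score_z_men = z * (1 - g),
                         score_z_women = z * g))
  if (include_site && length(unique(cv$site)) > 1L) {
    sizes <- table(cv$site)
    ref <- names(sizes)[which.max(sizes)]
    for (s in setdiff(names(sizes), ref))
      cols[[paste0("site", s)]] <- as.numeric(cv$site == as.integer(s))
  }
  X <- do.call(cbind, cols)
  rownames(X) <- cv$subject_id
  structure(list(X = X, subject_id = cv$subject_id, dropped = dropped,
                 score = score, type = type, include_site = include_site),
            class = "fdt_design")
}

#' Gender-specific-slope design
#'
#' Convenience wrapper for the "mathematically equivalent" reparameterized
#' design in which the score and interaction columns are replaced by
#' separate per-gender score columns.
#'
#' @inheritParams build_design
#' @return an \code{fdt_design} of type \code{gender_slopes}.
#' @export
gender_specific_design <- function(covariates, score, include_site = TRUE) {
  build_design(covariates, score, type = "gender_slopes",
               include_site = include_site)
}

#' @export
print.fdt_design <- function(x, ...) {
  cat(sprintf("FDT design (%s, score %s%s): %d subjects, columns: %s\n",
              x$type, x$score,
              if (x$include_site) ", site dummies" else "",
              nrow(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

## error if the (intercept-augmented) design is rank deficient, naming
## offending columns
.check_full_rank <- function(X) {
  Xi <- cbind(`(intercept)` = 1, X)
  q <- qr(Xi)
  if (q$rank < ncol(Xi)) {
    drop <- colnames(Xi)[q$pivot[(q$rank + 1L):ncol(Xi)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
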