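## Type-1 signal detection measures and confidence-count construction.

#' Map a raw confidence rating onto the common 1--10 scale
#'
#' Study sites collected confidence either directly on a 1--10 scale or on a
#' 0--100 visual-analogue-style scale. Ratings on the 0--100 dialect are
#' down-sampled into ten bins so that all sites share one scale: bin
#' \code{min(10, floor(raw / 10) + 1)}, i.e. 0--9 -> 1, 10--19 -> 2, ...,
#' 90--100 -> 10. Ratings already on 1--10 pass through unchanged.
#'
#' @param raw integer vector of raw confidence ratings.
#' @param dialect either \code{"1-10"} or \code{"0-100"}; recycled to the
#'   length of \code{raw}.
#' @return integer vector of confidence bins in 1..10.
#' @examples
#' bin_confidence(7, "1-10")
#' bin_confidence(c(0, 55, 100), "0-100")
#' @export
bin_confidence <- function(raw, dialect) {
  dialect <- match.arg(dialect, c("1-10", "0-100"), several.ok = TRUE)
  dialect <- rep_len(dialect, length(raw))
  out <- integer(length(raw))
  ten <- dialect == "1-10"
  bad10 <- ten & (is.na(raw) | raw < 1 | raw > 10)
  bad100 <- !ten & (is.na(raw) | raw < 0 | raw > 100)
  if (any(bad10 | bad100)) {
    v <- raw[which(bad10 | bad100)[1]]
    stop("confidence_out_of_range: raw confidence ", v,
         " outside declared scale bounds", call. = FALSE)
  }
  out[ten] <- as.integer(raw[ten])
  out[!ten] <- pmin(10L, as.integer(floor(raw[!ten] / 10)) + 1L)
  out
}

#' Perceptual threshold of one subject
#'
#' The threshold (interoceptive sensitivity) is the filter count at which the
#' subject completed their threshold block. With clean data all 60 threshold
#' trials sit at one filter number; with stragglers from difficulty changes
#' the modal filter count is used, ties broken toward the larger (easier)
#' filter number.
#'
#' @param trials data.frame with at least a \code{filter_count} column, all
#'   rows belonging to one subject.
#' @return integer filter count.
#' @export
estimate_threshold <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L)
    stop("no trials supplied", call. = FALSE)
  tab <- table(trials$filter_count)
  top <- as.integer(names(tab)[tab == max(tab)])
  max(top)
}

#' Type-1 signal detection estimates from confidence counts
#'
#' Computes hit rate (yes | present) and false-alarm rate (yes | absent) from
#' a confidence-count object, clamps each rate into
#' \eqn{[1/(2N), 1 - 1/(2N)]} (N = trials in that stimulus class) so the
#' normal quantiles stay finite, and returns the equal-variance Gaussian SDT
#' estimates \eqn{d' = z(HR) - z(FAR)} and \eqn{c = -(z(HR) + z(FAR))/2}.
#' Negative \eqn{c} indicates a bias towards reporting "yes" (over-reporting
#' the resistance).
#'
#' @param counts a \code{conf_counts} object from \code{\link{build_counts}}.
#' @return list of class \code{sdt_estimates}: \code{d_prime}, \code{c},
#'   \code{hit_rate}, \code{fa_rate}, \code{corrected} (TRUE if clamping
#'   changed a rate).
#' @export
estimate_type1 <- function(counts) {
  stopifnot(inherits(counts, "conf_counts"))
  n_absent <- sum(counts$n_s1)
  n_present <- sum(counts$n_s2)
  if (n_absent == 0L || n_present == 0L)
    stop("both stimulus classes must be observed to estimate d-prime",
         call. = FALSE)
  K <- length(counts$n_s1) / 2L
  hr_raw <- sum(counts$n_s2[(K + 1L):(2L * K)]) / n_present
  far_raw <- sum(counts$n_s1[(K + 1L):(2L * K)]) / n_absent
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  hr <- clamp(hr_raw, n_present)
  far <- clamp(far_raw, n_absent)
  structure(list(
    d_prime = qnorm(hr) - qnorm(far),
    c = -(qnorm(hr) + qnorm(far)) / 2,
    hit_rate = hr,
    fa_rate = far,
    corrected = (hr != hr_raw) || (far != far_raw)
  ), class = "sdt_estimates")
}

#' Metacognitive bias of one subject
#'
#' Mean confidence (on the common 1--10 binned scale) over the subject's
#' threshold-block trials, irrespective of accuracy.
#'
#' @param trials one subject's trials; needs \code{filter_count},
#'   \code{confidence_raw} and \code{scale_dialect} columns.
#' @param threshold the subject's threshold filter count.
#' @return numeric scalar in [1, 10].
#' @export
metacognitive_bias <- function(trials, threshold) {
  thr <- trials[trials$filter_count == threshold, , drop = FALSE]
  if (nrow(thr) == 0L)
    stop("no trials at the threshold filter count", call. = FALSE)
  mean(bin_confidence(thr$confidence_raw, thr$scale_dialect))
}

#' Response-conditional confidence counts for one subject
#'
#' Builds the 2K-cell count vectors consumed by the meta-d' likelihood, one
#' per stimulus class, using only threshold-block trials. Cells are ordered
#' from highest-confidence "no" to highest-confidence "yes": cell 1 is a
#' "no" response at confidence 10, cell K a "no" at confidence 1, cell K+1 a
#' "yes" at confidence 1, cell 2K a "yes" at confidence 10.
#'
#' @inheritParams metacognitive_bias
#' @param threshold threshold filter count; only trials at this filter count
#'   are used.
#' @return object of class \code{conf_counts}: integer vectors \code{n_s1}
#'   (stimulus absent) and \code{n_s2} (stimulus present) of length 2K
#'   (K = 10), plus \code{padded = FALSE}.
#' @export
build_counts <- function(trials, threshold) {
  thr <- trials[trials$filter_count == threshold, , drop = FALSE]
  if (nrow(thr) == 0L)
    stop("no trials at the threshold filter count", call. = FALSE)
  K <- 10L
  bin <- bin_confidence(thr$confidence_raw, thr$scale_dialect)
  cell <- ifelse(thr$response_yes == 1L, K + bin, K + 1L - bin)
  n_s1 <- tabulate(cell[thr$stimulus_present == 0L], nbins = 2L * K)
  n_s2 <- tabulate(cell[thr$stimulus_present == 1L], nbins = 2L * K)
  structure(list(n_s1 = n_s1, n_s2 = n_s2, padded = FALSE, K = K),
            class = "conf_counts")
}

#' Pad confidence counts for the maximum-likelihood path
#'
#' If any cell of the count vectors is zero, adds 1/(2K) to every cell so the
#' multinomial log-likelihood stays finite. Counts without zero cells are
#' returned unchanged.
#'
#' @param counts a \code{conf_counts} object.
#' @return a \code{conf_counts} object with \code{padded} set accordingly.
#' @export
pad_counts <- function(counts) {
  stopifnot(inherits(counts, "conf_counts"))
  if (any(c(counts$n_s1, counts$n_s2) == 0)) {
    eps <- 1 / (2 * counts$K)
    counts$n_s1 <- counts$n_s1 + eps
    counts$n_s2 <- counts$n_s2 + eps
    counts$padded <- TRUE
  }
  counts
}

#' @export
print.sdt_estimates <- function(x, ...) {
  cat(sprintf(
    "Type-1 SDT: d' = %.3f, c = %.3f (HR = %.3f, FAR = %.3f%s)\n",
    x$d_prime, x$c, x$hit_rate, x$fa_rate,
    if (x$corrected) ", rates clamped" else ""))
  invisible(x)
}

#' Per-subject interoceptive measures from trial-level FDT data
#'
#' For every subject in a trial table: the perceptual threshold, type-1
#' d-prime and decision bias, metacognitive bias, and the confidence-count
#' object needed by the meta-d' models. logMratio is left \code{NA} here and
#' filled by the hierarchical (or MLE) fit.
#'
#' @param trials data.frame with columns \code{subject_id},
#'   \code{trial_index}, \code{filter_count}, \code{stimulus_present},
#'   \code{response_yes}, \code{confidence_raw}, \code{scale_dialect}.
#' @return object of class \code{fdt_measures}: a data.frame (one row per
#'   subject: \code{subject_id}, \code{threshold_filters}, \code{d_prime},
#'   \code{decision_bias}, \code{metacog_bias}, \code{log_m_ratio}) with the
#'   per-subject \code{conf_counts} list attached as attribute
#'   \code{"counts"}.
#' @export
fdt_measures <- function(trials) {
  need <- c("subject_id", "filter_count", "stimulus_present",
            "response_yes", "confidence_raw", "scale_dialect")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(trials$subject_id)
  counts_list <- vector("list", length(ids))
  names(counts_list) <- as.character(ids)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- trials[trials$subject_id == ids[i], , drop = FALSE]
    thr <- estimate_threshold(tr)
    cnt <- build_counts(tr, thr)
    t1 <- estimate_type1(cnt)
    counts_list[[i]] <- cnt
    rows[[i]] <- data.frame(
      subject_id = ids[i],
      threshold_filters = thr,
      d_prime = t1$d_prime,
      decision_bias = t1$c,
      metacog_bias = metacognitive_bias(tr, thr),
      log_m_ratio = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "counts") <- counts_list
  class(out) <- c("fdt_measures", "data.frame")
  out
}

#' @export
print.fdt_measures <- function(x, ...) {
  cat("FDT interoceptive measures for", nrow(x), "subjects\n")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more subjects\n")
  invisible(x)
}
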