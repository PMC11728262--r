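## The FDT difficulty algorithm: practice, calibration, and the
## beta-distribution risk-controlled staircase, plus a simulated observer
## for testing it.

#' Probability that true accuracy lies inside the target band
#'
#' Cumulative accuracy (k correct of n) is transformed, under a uniform
#' Beta(1,1) prior, into the posterior Beta(1+k, 1+n-k) over the underlying
#' accuracy, and the probability mass inside [lower, upper] is returned via
#' the regularized incomplete beta function.
#'
#' @param k number of correct trials (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param lower,upper accuracy band (defaults 0.60 and 0.85).
#' @return probability in [0, 1].
#' @examples
#' band_probability(7, 10)  # ~ 0.63
#' @export
band_probability <- function(k, n, lower = 0.60, upper = 0.85) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  if (!(lower >= 0 && upper <= 1 && lower < upper))
    stop("invalid accuracy band", call. = FALSE)
  pbeta(upper, 1 + k, 1 + n - k) - pbeta(lower, 1 + k, 1 + n - k)
}

#' Fresh staircase state for the threshold phase
#'
#' @param start_filters starting filter count (from calibration).
#' @param lower,upper target accuracy band.
#' @param risk_threshold error-risk threshold for prompting a filter change.
#' @param trials_target trials to complete at one filter number.
#' @param auto_until trial count at the current filter up to which the
#'   automatic controller runs; past it, adjustments only happen at
#'   every \code{review_every}-trial manual review.
#' @param review_every interval of post-automatic manual reviews.
#' @return list of class \code{staircase_state}.
#' @export
staircase_init <- function(start_filters, lower = 0.60, upper = 0.85,
                           risk_threshold = 0.20, trials_target = 60L,
                           auto_until = 30L, review_every = 10L) {
  stopifnot(start_filters >= 1)
  structure(list(phase = "threshold",
                 current_filters = as.integer(start_filters),
                 trials_at_current = 0L, correct_at_current = 0L,
                 lower = lower, upper = upper,
                 risk_threshold = risk_threshold,
                 trials_target = as.integer(trials_target),
                 auto_until = as.integer(auto_until),
                 review_every = as.integer(review_every),
                 flags = character(0)),
            class = "staircase_state")
}

#' Advance the staircase by one threshold trial
#'
#' Updates the accuracy counts at the current filter number and decides the
#' next action. While the automatic controller is active (up to
#' \code{auto_until} trials at the current filter), a filter change is
#' prompted whenever the posterior probability of being inside the accuracy
#' band falls below the risk threshold: a filter is added if the lower tail
#' (accuracy below the band) dominates, removed if the upper tail dominates.
#' Counts reset at the new filter number. After \code{auto_until} trials
#' the automatic controller is disabled; at every
#' \code{review_every}-trial review where the band probability is below
#' the risk threshold, the experimenter's manual intervention is simulated
#' instead: the same filter-change decision is applied and logged as a
#' manual adjustment. The session stops once \code{trials_target} trials
#' are completed at one filter number.
#'
#' @param state a \code{\link{staircase_init}} state.
#' @param correct logical/0-1: was the trial answered correctly?
#' @return the updated state, with \code{$action} set to one of
#'   \code{"continue"}, \code{"add_filter"}, \code{"remove_filter"},
#'   \code{"stop"}.
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"),
            state$phase == "threshold")
  state$trials_at_current <- state$trials_at_current + 1L
  state$correct_at_current <- state$correct_at_current + as.integer(correct)
  n <- state$trials_at_current
  k <- state$correct_at_current

  if (n >= state$trials_target) {
    state$action <- "stop"
    return(state)
  }
  p_band <- band_probability(k, n, state$lower, state$upper)
  evaluate <- if (n <= state$auto_until) p_band < state$risk_threshold
              else n %% state$review_every == 0L &&
                   p_band < state$risk_threshold
  if (evaluate) {
    if (n > state$auto_until)
      state$flags <- c(state$flags,
                       sprintf("trial %d: accuracy %.2f outside tolerance; manual adjustment",
                               n, k / n))
    p_low <- pbeta(state$lower, 1 + k, 1 + n - k)
    p_high <- pbeta(state$upper, 1 + k, 1 + n - k, lower.tail = FALSE)
    if (p_low > p_high) {
      state$current_filters <- state$current_filters + 1L
      state$action <- "add_filter"
    } else {
      if (state$current_filters <= 1L) {
        state$flags <- c(state$flags,
                         sprintf("trial %d: removal requested at 1 filter; clamped", n))
        state$current_filters <- 1L
        state$action <- "continue"
        return(state)
      }
      state$current_filters <- state$current_filters - 1L
      state$action <- "remove_filter"
    }
    state$trials_at_current <- 0L
    state$correct_at_current <- 0L
    return(state)
  }
  state$action <- "continue"
  state
}

#' Simulated observer for the staircase
#'
#' Accuracy as a logistic function of filter count:
#' \eqn{P(correct | f) = 0.5 + (0.5 - lapse) \cdot logistic(slope (f - midpoint))},
#' monotone non-decreasing in filters and bounded in [0.5, 1 - lapse].
#'
#' @param midpoint filter count of the accuracy inflection.
#' @param slope logistic slope per filter.
#' @param lapse lapse rate (upper asymptote 1 - lapse).
#' @return list of class \code{sim_observer} with a \code{p_correct(f)}
#'   function.
#' @export
sim_observer <- function(midpoint = 4, slope = 1.5, lapse = 0.02) {
  stopifnot(lapse >= 0, lapse < 0.5, slope > 0)
  p_correct <- function(f)
    0.5 + (0.5 - lapse) / (1 + exp(-slope * (f - midpoint)))
  structure(list(midpoint = midpoint, slope = slope, lapse = lapse,
                 p_correct = p_correct), class = "sim_observer")
}

## one detection trial for the simulated observer; returns a trial log row
.observer_trial <- function(observer, filters, stimulus_present, phase,
                            idx) {
  pc <- observer$p_correct(filters)
  correct <- runif(1) < pc
  response_yes <- if (stimulus_present == 1L) as.integer(correct)
                  else as.integer(!correct)
  conf <- min(10L, max(1L, as.integer(round(1 + 9 * (pc - 0.5) / 0.5 +
                                              rnorm(1, 0, 1.5)))))
  data.frame(phase = phase, trial_index = idx, filter_count = filters,
             stimulus_present = stimulus_present, response_yes = response_yes,
             correct = as.integer(correct), confidence_raw = conf,
             scale_dialect = "1-10", stringsAsFactors = FALSE)
}

#' Calibration phase: find the starting filter number
#'
#' Starting from the dummy, filters are presented in ascending number (all
#' with the resistance present) until two consecutive presentations are
#' reported as detected. One final calibration trial is then run with one
#' filter fewer than the first of the two consecutive detections: if that
#' lower load is also detected, the threshold phase starts there, otherwise
#' at the first-of-two-consecutive value.
#'
#' @param observer a \code{\link{sim_observer}}.
#' @param seed integer seed (identical seed gives an identical trace).
#' @param ceiling maximum filter number tried before giving up.
#' @return list: \code{start_filters}, \code{log} (trial log data.frame).
#' @export
run_calibration <- function(observer, seed = 1L, ceiling = 12L) {
  stopifnot(inherits(observer, "sim_observer"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  res <- .calibrate(observer, ceiling)
  res
}

.calibrate <- function(observer, ceiling = 12L) {
  log <- list(); idx <- 0L
  consec <- 0L; first_of_pair <- NA_integer_
  f <- 1L
  repeat {
    if (f > ceiling)
      stop("no detection by the filter ceiling (", ceiling, ")",
           call. = FALSE)
    idx <- idx + 1L
    row <- .observer_trial(observer, f, 1L, "calibration", idx)
    log[[idx]] <- row
    if (row$response_yes == 1L) {
      consec <- consec + 1L
      if (consec == 1L) first_of_pair <- f
      if (consec == 2L) break
    } else {
      consec <- 0L
    }
    f <- f + 1L
  }
  check_f <- first_of_pair - 1L
  if (check_f >= 1L) {
    idx <- idx + 1L
    row <- .observer_trial(observer, check_f, 1L, "calibration", idx)
    log[[idx]] <- row
    start <- if (row$response_yes == 1L) check_f else first_of_pair
  } else {
    start <- first_of_pair
  }
  list(start_filters = start, log = do.call(rbind, log))
}

.practice <- function(observer, ceiling = 12L) {
  log <- list(); idx <- 1L
  ## explicit dummy: sham filter, participant is told
  log[[1]] <- data.frame(phase = "practice", trial_index = 1L,
                         filter_count = 0L, stimulus_present = 0L,
                         response_yes = 0L, correct = 1L,
                         confidence_raw = 10L, scale_dialect = "1-10",
                         stringsAsFactors = FALSE)
  f <- 7L
  repeat {
    idx <- idx + 1L
    row <- .observer_trial(observer, f, 1L, "practice", idx)
    log[[idx]] <- row
    if (row$response_yes == 1L) break
    f <- f + 1L
    if (f > ceiling)
      stop("no detection by the filter ceiling (", ceiling,
           ") during practice", call. = FALSE)
  }
  do.call(rbind, log)
}

#' Simulate a full FDT session
#'
#' Runs practice (explicit dummy, then a 7-filter trial with filters added
#' until a resistance is reported), calibration, and the risk-controlled
#' threshold phase to completion. The threshold-phase log is compatible with
#' \code{\link{fdt_measures}}.
#'
#' @param observer a \code{\link{sim_observer}}.
#' @param seed integer seed.
#' @param max_trials maximum threshold trials before the session is flagged
#'   as non-converged.
#' @param subject_id id written into the trial log.
#' @param ... passed to \code{\link{staircase_init}}.
#' @return list of class \code{fdt_session}: \code{trials} (threshold-phase
#'   log with a \code{subject_id} column), \code{pre_log} (practice +
#'   calibration), \code{final_filters}, \code{final_accuracy} (empirical
#'   accuracy over the completed threshold block), \code{completed},
#'   \code{flags}.
#' @export
simulate_session <- function(observer, seed = 1L, max_trials = 200L,
                             subject_id = "sim01", ...) {
  stopifnot(inherits(observer, "sim_observer"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  pre <- .practice(observer)
  cal <- .calibrate(observer)
  cal$log$trial_index <- cal$log$trial_index + nrow(pre)
  pre <- rbind(pre, cal$log)

  state <- staircase_init(cal$start_filters, ...)
  rows <- list(); idx <- 0L
  completed <- FALSE
  while (idx < max_trials) {
    idx <- idx + 1L
    stim <- rbinom(1, 1, 0.5)
    row <- .observer_trial(observer, state$current_filters, stim,
                           "threshold", idx)
    rows[[idx]] <- row
    state <- staircase_step(state, row$correct)
    if (state$action == "stop") { completed <- TRUE; break }
  }
  trials <- do.call(rbind, rows)
  trials <- cbind(subject_id = subject_id, trials,
                  stringsAsFactors = FALSE)
  acc <- if (completed)
    state$correct_at_current / state$trials_at_current else NA_real_
  if (!completed)
    state$flags <- c(state$flags,
                     sprintf("session did not complete within %d trials",
                             max_trials))
  structure(list(trials = trials, pre_log = pre,
                 final_filters = state$current_filters,
                 final_accuracy = acc, completed = completed,
                 flags = state$flags, observer = observer, seed = seed),
            class = "fdt_session")
}

#' @export
print.fdt_session <- function(x, ...) {
  cat(sprintf(
    "FDT session (observer midpoint %.1f): %s, final filters %d, accuracy %s\n",
    x$observer$midpoint,
    if (x$completed) "completed" else "NOT completed",
    x$final_filters,
    if (is.na(x$final_accuracy)) "NA" else sprintf("%.2f", x$final_accuracy)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
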