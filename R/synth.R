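## Synthetic FDT cohorts with planted covariate effects.
##
## The generator emulates the pooled multicentre study conditions: 175
## subjects over four sites (78/30/30/37), 51% women, 60 threshold trials
## per subject, confidence collected on two scale dialects, and planted
## linear relationships between z-scored state anxiety and (a) subject
## logMratio, with a gender-specific slope, and (b) mean confidence.

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the emulated study conditions: cohort composition as in the
#' pooled multicentre sample; type-1 sensitivity around d' = 1.2 (mid 60--85\%
#' accuracy band); unbiased criterion on average; population logMratio -0.1
#' with gender-specific anxiety slopes -0.18 (women) and 0.02 (men); mean
#' confidence level near 6.4 bins with slope -0.28 bins per anxiety SD.
#'
#' @param n_subjects number of subjects.
#' @param prop_women fraction of women in [0,1]; gender coded 0 = man,
#'   1 = woman.
#' @param site_sizes integer vector summing to \code{n_subjects}.
#' @param n_trials threshold trials per subject.
#' @param p_stimulus per-trial probability that the resistance is present.
#' @param d_prime_mean,d_prime_sd generative distribution of type-1
#'   sensitivity (truncated below at 0.2).
#' @param c_mean,c_sd generative distribution of the decision criterion.
#' @param mu_logM population mean logMratio.
#' @param beta_anx_logM_men,beta_anx_logM_women generative slopes of subject
#'   logMratio on z-scored state anxiety, per gender.
#' @param sigma_logM subject-level residual SD of logMratio (>= 0).
#' @param conf_baseline baseline shift of confidence bins (places mean
#'   confidence mid-scale).
#' @param conf_bias_slope slope of the subject confidence offset on z-scored
#'   state anxiety, in bins per SD.
#' @param conf_noise_sd subject-level residual SD of the confidence offset.
#' @param confidence_scale_dialect character vector, one of \code{"1-10"} or
#'   \code{"0-100"} per site.
#' @param seed integer seed; same seed and config give identical tables.
#' @return validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 175L,
                         prop_women = 0.51,
                         site_sizes = c(78L, 30L, 30L, 37L),
                         n_trials = 60L,
                         p_stimulus = 0.5,
                         d_prime_mean = 1.2,
                         d_prime_sd = 0.3,
                         c_mean = 0,
                         c_sd = 0.2,
                         mu_logM = -0.1,
                         beta_anx_logM_men = 0.02,
                         beta_anx_logM_women = -0.18,
                         sigma_logM = 0.25,
                         conf_baseline = 3,
                         conf_bias_slope = -0.28,
                         conf_noise_sd = 0.75,
                         confidence_scale_dialect = c("1-10", "0-100",
                                                      "1-10", "1-10"),
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), prop_women = prop_women,
              site_sizes = as.integer(site_sizes),
              n_trials = as.integer(n_trials), p_stimulus = p_stimulus,
              d_prime_mean = d_prime_mean, d_prime_sd = d_prime_sd,
              c_mean = c_mean, c_sd = c_sd, mu_logM = mu_logM,
              beta_anx_logM_men = beta_anx_logM_men,
              beta_anx_logM_women = beta_anx_logM_women,
              sigma_logM = sigma_logM, conf_baseline = conf_baseline,
              conf_bias_slope = conf_bias_slope,
              conf_noise_sd = conf_noise_sd,
              confidence_scale_dialect = confidence_scale_dialect,
              seed = as.integer(seed))
  bad <- function(msg) stop("invalid_config: ", msg, call. = FALSE)
  if (sum(cfg$site_sizes) != cfg$n_subjects)
    bad("site_sizes must sum to n_subjects")
  if (cfg$prop_women < 0 || cfg$prop_women > 1)
    bad("prop_women must be in [0,1]")
  if (cfg$p_stimulus < 0 || cfg$p_stimulus > 1)
    bad("p_stimulus must be in [0,1]")
  if (cfg$n_trials < 1L) bad("n_trials must be >= 1")
  if (cfg$d_prime_sd < 0) bad("d_prime_sd must be >= 0")
  if (cfg$c_sd < 0) bad("c_sd must be >= 0")
  if (cfg$sigma_logM < 0) bad("sigma_logM must be >= 0")
  if (cfg$conf_noise_sd < 0) bad("conf_noise_sd must be >= 0")
  if (length(cfg$confidence_scale_dialect) != length(cfg$site_sizes))
    bad("confidence_scale_dialect needs one entry per site")
  if (!all(cfg$confidence_scale_dialect %in% c("1-10", "0-100")))
    bad("confidence_scale_dialect entries must be '1-10' or '0-100'")
  structure(cfg, class = "synth_config")
}

## truncated-normal integers on an instrument's range
.trunc_int <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, round(rnorm(n, mean, sd))))
}

## type-2 generative criteria: K-1 cuts equally spaced between the scaled
## criterion and +/-3 evidence units
.gen_cuts <- function(cprime) {
  hi <- max(3, cprime + 0.5)
  lo <- min(-3, cprime - 0.5)
  list(yes = cprime + (1:9) / 10 * (hi - cprime),
       no = cprime - (1:9) / 10 * (cprime - lo))
}

#' Simulate a synthetic FDT cohort
#'
#' Draws subject covariates and trial-level detection data from the
#' equal-variance Gaussian SDT generative model. Each trial: the stimulus is
#' present with probability \code{p_stimulus}; a type-1 evidence sample from
#' \eqn{N(\pm d'/2, 1)} is compared with the criterion \eqn{c}; confidence
#' comes from a second, metacognitive evidence sample with sensitivity
#' meta-d' \eqn{= d' e^{logMratio_s}} (redrawn until it falls on the same
#' response side of the scaled criterion), binned through ordered type-2
#' criteria and shifted by the subject's confidence offset. Subject
#' logMratio is \code{mu_logM} plus the gender-specific anxiety slope times
#' z-scored state anxiety plus Gaussian noise.
#'
#' @param config a \code{\link{synth_config}} object.
#' @param seed optional override of \code{config$seed}.
#' @return list of class \code{fdt_cohort}: \code{covariates} (subject_id,
#'   gender, site, stai_state, stai_trait, cesd), \code{trials} (one row per
#'   trial, analysis input), and \code{truth} (generative subject parameters;
#'   for recovery checks only, never consumed by the analysis functions).
#' @export
simulate_cohort <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(seed)) seed <- config$seed
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  n <- config$n_subjects
  site <- rep(seq_along(config$site_sizes), config$site_sizes)
  n_women <- round(config$prop_women * n)
  gender <- integer(n)
  gender[sample.int(n, n_women)] <- 1L

  stai_state <- .trunc_int(n, 35, 10, 20, 80)
  stai_trait <- pmin(80, pmax(20, round(35 + 0.7 * (stai_state - 35) +
                                          rnorm(n, 0, 7))))
  cesd <- pmin(60, pmax(0, round(10 + 0.5 * (stai_state - 35) +
                                   rnorm(n, 0, 7))))
  anx_z <- if (n > 1L && sd(stai_state) > 0)
    as.numeric(scale(stai_state)) else numeric(n)

  d <- pmax(0.2, rnorm(n, config$d_prime_mean, config$d_prime_sd))
  cc <- rnorm(n, config$c_mean, config$c_sd)
  slope <- ifelse(gender == 1L, config$beta_anx_logM_women,
                  config$beta_anx_logM_men)
  logM <- config$mu_logM + slope * anx_z + rnorm(n, 0, config$sigma_logM)
  conf_offset <- config$conf_baseline + config$conf_bias_slope * anx_z +
    rnorm(n, 0, config$conf_noise_sd)
  threshold <- sample(2:6, n, replace = TRUE,
                      prob = c(0.15, 0.3, 0.3, 0.15, 0.1))

  trial_rows <- vector("list", n)
  for (s in seq_len(n)) {
    nt <- config$n_trials
    metad <- d[s] * exp(logM[s])
    cprime <- cc[s] * metad / d[s]
    stim <- rbinom(nt, 1L, config$p_stimulus)
    x1 <- rnorm(nt, ifelse(stim == 1L, d[s] / 2, -d[s] / 2), 1)
    resp <- as.integer(x1 > cc[s])
    mu2 <- ifelse(stim == 1L, metad / 2, -metad / 2)
    x2 <- rnorm(nt, mu2, 1)
    bad <- (x2 > cprime) != (resp == 1L)
    while (any(bad)) {
      x2[bad] <- rnorm(sum(bad), mu2[bad], 1)
      bad <- (x2 > cprime) != (resp == 1L)
    }
    cuts <- .gen_cuts(cprime)
    bin <- integer(nt)
    yes <- resp == 1L
    bin[yes] <- 1L + as.integer(rowSums(outer(x2[yes], cuts$yes, `>`)))
    bin[!yes] <- 1L + as.integer(rowSums(outer(x2[!yes], cuts$no, `<`)))
    bin <- pmin(10L, pmax(1L, bin + as.integer(round(conf_offset[s]))))
    dialect <- config$confidence_scale_dialect[site[s]]
    if (dialect == "0-100") {
      jit <- sample(0:9, nt, replace = TRUE)
      jit[bin == 10L] <- sample(0:10, sum(bin == 10L), replace = TRUE)
      raw <- (bin - 1L) * 10L + jit
    } else raw <- bin
    trial_rows[[s]] <- data.frame(
      subject_id = sprintf("S%03d", s),
      trial_index = seq_len(nt),
      filter_count = threshold[s],
      stimulus_present = stim,
      response_yes = resp,
      confidence_raw = as.integer(raw),
      scale_dialect = dialect,
      stringsAsFactors = FALSE)
  }

  ids <- sprintf("S%03d", seq_len(n))
  structure(list(
    covariates = data.frame(subject_id = ids, gender = gender, site = site,
                            stai_state = stai_state, stai_trait = stai_trait,
                            cesd = cesd, stringsAsFactors = FALSE),
    trials = do.call(rbind, trial_rows),
    truth = data.frame(subject_id = ids, true_d_prime = d, true_c = cc,
                       true_log_m_ratio = logM, true_conf_offset = conf_offset,
                       true_threshold = threshold, anx_z = anx_z,
                       stringsAsFactors = FALSE),
    config = config, seed = seed
  ), class = "fdt_cohort")
}

#' @export
print.fdt_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic FDT cohort: %d subjects, %d sites, %d trials/subject (seed %d)\n",
    nrow(x$covariates), length(unique(x$covariates$site)),
    x$config$n_trials, x$seed))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes \code{covariates.csv}, \code{trials.csv} and \code{truth.csv}
#' (UTF-8, comma-delimited, header row) into \code{dir}.
#'
#' @param cohort an \code{fdt_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fdt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(cohort$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read analysis inputs back from CSV files
#'
#' Reads \code{covariates.csv} and \code{trials.csv}. The truth table, if
#' present, is deliberately not read: generative truth is only for recovery
#' tests, never for analysis.
#'
#' @param dir directory containing the files.
#' @return list with \code{covariates} and \code{trials} data.frames.
#' @export
read_cohort <- function(dir) {
  cov_f <- file.path(dir, "covariates.csv")
  tri_f <- file.path(dir, "trials.csv")
  if (!file.exists(cov_f) || !file.exists(tri_f))
    stop("expected covariates.csv and trials.csv in ", dir, call. = FALSE)
  list(covariates = read.csv(cov_f, stringsAsFactors = FALSE),
       trials = read.csv(tri_f, stringsAsFactors = FALSE))
}
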