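## End-to-end orchestration: simulate or ingest -> measures -> regressions
## -> report bundle.

#' Pipeline run configuration
#'
#' @param mode \code{"simulate"} (generate a synthetic cohort) or
#'   \code{"ingest"} (read \code{covariates.csv} / \code{trials.csv} from
#'   \code{input_dir}).
#' @param input_dir directory with input CSVs (ingest mode).
#' @param synth a \code{\link{synth_config}} (simulate mode).
#' @param scores psychological scores to analyse.
#' @param gender_models also fit the gender-interaction and
#'   gender-specific-slope models.
#' @param sensitivity_no_site also fit the site-collapsed OLS sensitivity
#'   models.
#' @param insight_designs design types for the hierarchical logMratio
#'   regression.
#' @param insight_sensitivity also fit the hierarchical models without site
#'   dummies.
#' @param mcmc an \code{\link{mcmc_control}} for the hierarchical fits.
#' @param seed integer master seed (simulation and MCMC seeds derive from
#'   it).
#' @param out_dir optional output directory for the report files.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(mode = c("simulate", "ingest"), input_dir = NULL,
                       synth = synth_config(),
                       scores = c("stai_state", "stai_trait", "cesd"),
                       gender_models = TRUE, sensitivity_no_site = TRUE,
                       insight_designs = c("base", "gender", "gender_slopes"),
                       insight_sensitivity = FALSE,
                       mcmc = mcmc_control(), seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(input_dir))
    stop("ingest mode needs input_dir", call. = FALSE)
  structure(list(mode = mode, input_dir = input_dir, synth = synth,
                 scores = scores, gender_models = gender_models,
                 sensitivity_no_site = sensitivity_no_site,
                 insight_designs = insight_designs,
                 insight_sensitivity = insight_sensitivity,
                 mcmc = mcmc, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Entries in the YAML file override the \code{\link{run_config}} defaults;
#' \code{synth:} and \code{mcmc:} sub-maps override the corresponding
#' sub-configuration fields.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- do.call(synth_config, as.list(y$synth %||% list()))
  mcmc <- do.call(mcmc_control, as.list(y$mcmc %||% list()))
  y$synth <- NULL; y$mcmc <- NULL
  do.call(run_config, c(y, list(synth = synth, mcmc = mcmc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a  # also used by exec/respmeta

## rolling polynomial hash (mod 2^31 - 1) for the manifest's config
## fingerprint; stays inside exact double-integer arithmetic
.config_fingerprint <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.required_trial_cols <- c("subject_id", "trial_index", "filter_count",
                          "stimulus_present", "response_yes",
                          "confidence_raw", "scale_dialect")

#' Run the full analysis pipeline
#'
#' Produces, per score: OLS suites for interoceptive sensitivity
#' (perceptual threshold), decision bias and metacognitive bias, and
#' hierarchical Bayesian regressions of logMratio (metacognitive insight)
#' for the requested designs; plus a combined long-format summary table in
#' which OLS rows carry two-tailed p-values and insight rows carry 95\% HDIs
#' with the excludes-zero flag.
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{fdt_report}: list with \code{measures},
#'   \code{ols} (nested list score -> measure -> \code{fdt_glm_suite}),
#'   \code{insight} (score -> design -> \code{hmetad}), \code{table}
#'   (long-format summary data.frame), \code{log} (captured warnings),
#'   \code{manifest}. If \code{config$out_dir} is set, writes
#'   \code{table1_like.csv}, \code{regression_report.json},
#'   \code{subject_measures.csv} and \code{manifest.json} there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$synth, seed = config$seed)
    covariates <- cohort$covariates
    trials <- cohort$trials
  } else {
    inp <- read_cohort(config$input_dir)
    covariates <- inp$covariates
    trials <- inp$trials
  }
  miss <- setdiff(.required_trial_cols, names(trials))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("subject_id", "gender", "site"), names(covariates))
  if (length(miss))
    stop("covariate table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)

  measures <- fdt_measures(trials)

  ols_measures <- c(sensitivity = "threshold_filters",
                    decision_bias = "decision_bias",
                    metacog_bias = "metacog_bias")
  ols <- list(); insight <- list()
  for (score in config$scores) {
    if (!score %in% names(covariates)) {
      note(sprintf("score '%s' absent from covariates; skipped", score))
      next
    }
    ols[[score]] <- list()
    for (m in names(ols_measures)) {
      ols[[score]][[m]] <- withCallingHandlers(
        run_measure_suite(measures, covariates, ols_measures[[m]], score),
        warning = function(w) {
          note(sprintf("[ols %s/%s] %s", score, m, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    }
    insight[[score]] <- list()
    designs <- config$insight_designs
    if (!config$gender_models) designs <- intersect(designs, "base")
    site_opts <- c(TRUE, if (config$insight_sensitivity) FALSE)
    for (with_site in site_opts) {
      for (dtype in designs) {
        key <- paste0(dtype, if (!with_site) "_no_site")
        res <- tryCatch(withCallingHandlers({
          des <- build_design(covariates, score, type = dtype,
                              include_site = with_site)
          fit_metad_hier(measures, des, mcmc = config$mcmc)
        }, warning = function(w) {
          note(sprintf("[insight %s/%s] %s", score, key,
                       conditionMessage(w)))
          invokeRestart("muffleWarning")
        }), error = function(e) {
          note(sprintf("[insight %s/%s] FAILED: %s", score, key,
                       conditionMessage(e)))
          NULL
        })
        insight[[score]][[key]] <- res
      }
    }
  }

  table <- .report_table(ols, insight)
  manifest <- list(
    package = "respmeta",
    version = as.character(utils::packageVersion("respmeta")),
    r_version = R.version.string,
    seed = config$seed,
    mode = config$mode,
    config_hash = .config_fingerprint(jsonlite::toJSON(
      config[setdiff(names(config), "out_dir")],
      auto_unbox = TRUE, force = TRUE)),
    timestamp = format(Sys.time(), tz = "UTC"))

  report <- structure(list(measures = measures, ols = ols,
                           insight = insight, table = table, log = log,
                           manifest = manifest, config = config),
                      class = "fdt_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

## long-format summary table mixing OLS p-values and insight HDIs
.report_table <- function(ols, insight) {
  rows <- list()
  add <- function(measure, score, model, term, estimate, p = NA_real_,
                  lo = NA_real_, hi = NA_real_, sig = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, score = score, model = model, term = term,
      estimate = estimate, p_value = p, hdi_low = lo, hdi_high = hi,
      significant = sig,
      inference = if (is.na(p)) "hdi" else "ols",
      stringsAsFactors = FALSE)
  }
  for (score in names(ols)) {
    for (m in names(ols[[score]])) {
      suite <- ols[[score]][[m]]
      for (tag in c("base", "gender", "gender_slopes",
                    "sensitivity_base", "sensitivity_gender")) {
        cf <- suite[[tag]]$coefficients
        for (i in seq_len(nrow(cf)))
          add(m, score, tag, cf$term[i], cf$estimate[i], p = cf$p[i],
              sig = cf$p[i] < 0.05)
      }
    }
  }
  for (score in names(insight)) {
    for (key in names(insight[[score]])) {
      fit <- insight[[score]][[key]]
      if (is.null(fit)) next
      sm <- fit$summary
      for (i in seq_len(nrow(sm)))
        add("insight", score, key, sm$param[i], sm$mean[i],
            lo = sm$hdi_low[i], hi = sm$hdi_high[i],
            sig = sm$excludes_zero[i])
    }
  }
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' @param report an \code{fdt_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fdt_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$table, file.path(dir, "table1_like.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$measures),
            file.path(dir, "subject_measures.csv"), row.names = FALSE)
  insight_summ <- lapply(report$insight, function(per_score)
    lapply(per_score, function(fit)
      if (!is.null(fit)) fit$summary))
  jsonlite::write_json(
    list(table = report$table, insight = insight_summ, log = report$log),
    file.path(dir, "regression_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.fdt_report <- function(x, ...) {
  cat("FDT analysis report\n")
  cat("  subjects:", nrow(x$measures), "\n")
  cat("  scores:", paste(names(x$ols), collapse = ", "), "\n")
  ins <- unlist(lapply(x$insight, names))
  cat("  insight fits:", if (length(ins)) length(ins) else 0, "\n")
  if (length(x$log)) cat("  log entries:", length(x$log), "\n")
  invisible(x)
}
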