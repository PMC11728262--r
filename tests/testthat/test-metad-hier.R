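## small shared cohort for structural tests
hier_cohort <- function(n = 10, trials = 60, seed = 6, ...) {
  cfg <- synth_config(n_subjects = n, site_sizes = n, prop_women = 0.5,
                      n_trials = trials,
                      confidence_scale_dialect = "1-10", seed = seed, ...)
  coh <- simulate_cohort(cfg)
  list(cohort = coh, measures = fdt_measures(coh$trials))
}

tiny_mcmc <- function(seed = 1)
  mcmc_control(n_chains = 1, n_adapt = 300, n_burnin = 200, n_iter = 500,
               seed = seed)

test_that("hierarchical fit returns a complete, reproducible object", {
  hc <- hier_cohort(8)
  f1 <- fit_metad_hier(hc$measures, mcmc = tiny_mcmc())
  f2 <- fit_metad_hier(hc$measures, mcmc = tiny_mcmc())
  expect_s3_class(f1, "hmetad")
  expect_identical(f1$draws_matrix, f2$draws_matrix)  # seeded determinism
  expect_setequal(c("mu_logM", "sigma_logM"), f1$summary$param)
  expect_true(all(c("mu_logM", "sigma_logM",
                    paste0("logM_", hc$measures$subject_id)) %in%
                    colnames(f1$draws_matrix)))
  expect_length(f1$subject_logM, 8)
  expect_true(all(f1$summary$hdi_low <= f1$summary$mean &
                    f1$summary$mean <= f1$summary$hdi_high))
  expect_type(f1$diagnostics$converged, "logical")
})

test_that("subject estimates shrink towards the group mean relative to MLEs", {
  hc <- hier_cohort(12, seed = 8)
  fit <- fit_metad_hier(hc$measures,
                        mcmc = mcmc_control(n_chains = 1, n_adapt = 600,
                                            n_burnin = 400, n_iter = 1500,
                                            seed = 2))
  cnts <- attr(hc$measures, "counts")
  mles <- vapply(seq_len(12), function(s)
    fit_metad_mle(cnts[[s]], hc$measures$d_prime[s],
                  hc$measures$decision_bias[s])$log_m_ratio, numeric(1))
  expect_lt(var(fit$subject_logM), var(mles))
})

test_that("degenerate and non-performing subjects are excluded with a warning", {
  hc <- hier_cohort(6, seed = 4)
  tr <- hc$cohort$trials
  ## subject A: constant confidence (no type-2 information)
  tr$confidence_raw[tr$subject_id == "S001"] <- 5L
  ## subject B: systematically wrong (negative d')
  sel <- tr$subject_id == "S002"
  tr$response_yes[sel] <- 1L - tr$stimulus_present[sel]
  m <- fdt_measures(tr)
  expect_warning(fit <- fit_metad_hier(m, mcmc = tiny_mcmc()),
                 "excluded 2 subject")
  expect_equal(fit$n_subjects, 4)
  expect_false(any(grepl("S001|S002", names(fit$subject_logM))))
})

test_that("gender designs yield contrast draws and consistent slopes", {
  cfg <- synth_config(n_subjects = 30, site_sizes = 30L, prop_women = 0.5,
                      beta_anx_logM_men = 0, beta_anx_logM_women = -0.4,
                      sigma_logM = 0.1,
                      confidence_scale_dialect = "1-10", seed = 15)
  coh <- simulate_cohort(cfg)
  m <- fdt_measures(coh$trials)
  ctl <- mcmc_control(n_chains = 1, n_adapt = 800, n_burnin = 700,
                      n_iter = 3000, seed = 5)
  des_int <- build_design(coh$covariates, "stai_state", "gender",
                          include_site = FALSE)
  f_int <- fit_metad_hier(m, des_int, mcmc = ctl)
  expect_true(all(c("slope_men", "slope_women") %in% f_int$summary$param))
  sm <- f_int$summary
  ## the interaction design's women slope is slope + interaction by algebra
  expect_equal(sm$mean[sm$param == "slope_women"],
               sm$mean[sm$param == "beta_score_z"] +
                 sm$mean[sm$param == "beta_score_z_x_gender"],
               tolerance = 1e-12)
  ## the reparameterized design recovers the same women slope
  des_gs <- gender_specific_design(coh$covariates, "stai_state",
                                   include_site = FALSE)
  f_gs <- fit_metad_hier(m, des_gs, mcmc = ctl)
  expect_true("interaction_women_minus_men" %in% f_gs$summary$param)
  w_int <- sm$mean[sm$param == "slope_women"]
  w_gs <- f_gs$summary$mean[f_gs$summary$param == "beta_score_z_women"]
  expect_lt(abs(w_int - w_gs), 0.05)
})

test_that("a mismatched or collinear design is rejected", {
  hc <- hier_cohort(6, seed = 10)
  des <- build_design(hc$cohort$covariates, "stai_state", "base",
                      include_site = FALSE)
  des$subject_id <- c(des$subject_id[-1], "GHOST")
  expect_error(fit_metad_hier(hc$measures, des, mcmc = tiny_mcmc()),
               "absent")
  des2 <- build_design(hc$cohort$covariates, "stai_state", "base",
                       include_site = FALSE)
  des2$X <- cbind(des2$X, score_z2 = des2$X[, "score_z"])
  expect_error(fit_metad_hier(hc$measures, des2, mcmc = tiny_mcmc()),
               "rank deficient")
})

test_that("beta's posterior spread shrinks as trials per subject grow", {
  sds <- vapply(c(20, 60, 200), function(nt) {
    cfg <- synth_config(n_subjects = 24, site_sizes = 24L, prop_women = 0.5,
                        n_trials = nt, beta_anx_logM_men = 0,
                        beta_anx_logM_women = 0, sigma_logM = 0.1,
                        confidence_scale_dialect = "1-10", seed = 33)
    coh <- simulate_cohort(cfg)
    m <- fdt_measures(coh$trials)
    des <- build_design(coh$covariates, "stai_state", "base",
                        include_site = FALSE)
    f <- suppressWarnings(fit_metad_hier(m, des,
          mcmc = mcmc_control(n_chains = 1, n_adapt = 600, n_burnin = 400,
                              n_iter = 1200, seed = 33)))
    sd(f$draws_matrix[, "beta_score_z"])
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("the native sampler matches an independent JAGS implementation", {
  cfg <- synth_config(n_subjects = 6, site_sizes = 6L, prop_women = 0.5,
                      n_trials = 150, mu_logM = -0.15, sigma_logM = 0.15,
                      beta_anx_logM_men = 0, beta_anx_logM_women = 0,
                      confidence_scale_dialect = "1-10", seed = 77)
  m <- fdt_measures(simulate_cohort(cfg)$trials)
  native <- fit_metad_hier(m, mcmc = mcmc_control(n_chains = 2,
                                                  n_adapt = 2000,
                                                  n_burnin = 2000,
                                                  n_iter = 8000, seed = 3))
  ref <- jags_hier_reference(m)
  nat <- coef(native)
  expect_lt(abs(nat[["mu_logM"]] - ref[["mu"]]), 0.1)
  expect_lt(abs(nat[["sigma_logM"]] - ref[["sigma"]]), 0.1)
})
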