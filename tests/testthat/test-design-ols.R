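toy_covariates <- function() {
  data.frame(subject_id = sprintf("S%02d", 1:8),
             gender = c(0, 0, 0, 0, 1, 1, 1, 1),
             site = c(1, 1, 1, 2, 1, 1, 2, 2),
             stai_state = c(30, 40, 50, 35, 25, 45, 55, 38),
             stringsAsFactors = FALSE)
}

test_that("designs z-score the covariate and code gender and site as promised", {
  des <- build_design(toy_covariates(), "stai_state", "gender")
  z <- des$X[, "score_z"]
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_setequal(colnames(des$X),
                  c("score_z", "gender", "score_z_x_gender", "site2"))
  expect_equal(unname(des$X[, "score_z_x_gender"]),
               unname(z * des$X[, "gender"]))
  ## largest site is the reference: no site1 dummy
  expect_false("site1" %in% colnames(des$X))
})

test_that("gender-specific design zeroes the opposite gender's score column", {
  des <- gender_specific_design(toy_covariates(), "stai_state",
                                include_site = FALSE)
  men <- des$X[, "gender"] == 0
  expect_true(all(des$X[!men, "score_z_men"] == 0))
  expect_true(all(des$X[men, "score_z_women"] == 0))
  expect_true(all(des$X[men, "score_z_men"] != 0))
})

test_that("interaction and gender-specific designs span the same space", {
  cv <- toy_covariates()
  A <- cbind(1, build_design(cv, "stai_state", "gender")$X)
  B <- cbind(1, build_design(cv, "stai_state", "gender_slopes")$X)
  PA <- A %*% solve(crossprod(A)) %*% t(A)
  PB <- B %*% solve(crossprod(B)) %*% t(B)
  expect_lt(max(abs(PA - PB)), 1e-10)
})

test_that("missing covariates are dropped listwise with a warning", {
  cv <- toy_covariates()
  cv$stai_state[c(2, 5)] <- NA
  expect_warning(des <- build_design(cv, "stai_state", "base"),
                 "2 subject")
  expect_equal(nrow(des$X), 6)
  expect_setequal(des$dropped, c("S02", "S05"))
  expect_error(build_design(cv, "nope", "base"), "not found")
})

test_that("OLS reproduces hand-computed normal-equation solutions", {
  ## perfect line (summary.lm warns about the zero-residual fit)
  f <- suppressWarnings(fit_ols(c(1, 2, 3), cbind(x = c(1, 2, 3))))
  expect_equal(coef(f)[["x"]], 1, tolerance = 1e-12)
  expect_equal(coef(f)[["intercept"]], 0, tolerance = 1e-12)
  ## four points worked by hand: slope 1.9, intercept 0
  f <- fit_ols(c(2, 4, 5, 8), cbind(x = 1:4))
  expect_equal(coef(f)[["x"]], 1.9, tolerance = 1e-12)
  expect_equal(coef(f)[["intercept"]], 0, tolerance = 1e-10)
  expect_equal(f$df_residual, 2)
  expect_true(all(f$coefficients$p >= 0 & f$coefficients$p <= 1))
})

test_that("OLS is invariant to row permutations and rejects collinearity", {
  set.seed(12)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  y <- 1 + X %*% c(0.5, -1) + rnorm(20, 0, 0.3)
  f1 <- fit_ols(y, X)
  p <- sample(20)
  f2 <- fit_ols(y[p], X[p, ])
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(f1$coefficients$p, f2$coefficients$p, tolerance = 1e-12)
  expect_error(fit_ols(y, cbind(X, a2 = X[, "a"])), "a2")
})

test_that("the five-model suite is internally consistent", {
  cfg <- synth_config(n_subjects = 80, site_sizes = c(40, 40),
                      prop_women = 0.5, n_trials = 20,
                      confidence_scale_dialect = c("1-10", "0-100"),
                      seed = 19)
  coh <- simulate_cohort(cfg)
  m <- fdt_measures(coh$trials)
  suite <- run_measure_suite(m, coh$covariates, "metacog_bias", "stai_state")
  expect_setequal(
    intersect(names(suite), c("base", "gender", "gender_slopes",
                              "sensitivity_base", "sensitivity_gender")),
    c("base", "gender", "gender_slopes", "sensitivity_base",
      "sensitivity_gender"))
  ## same span: identical fitted values across the two gender designs
  expect_lt(max(abs(fitted(suite$gender$fit) -
                      fitted(suite$gender_slopes$fit))), 1e-10)
  ## coefficient mapping: men slope = score slope; women = slope + interaction
  cg <- coef(suite$gender)
  cs <- coef(suite$gender_slopes)
  expect_equal(cs[["score_z_men"]], cg[["score_z"]], tolerance = 1e-10)
  expect_equal(cs[["score_z_women"]],
               cg[["score_z"]] + cg[["score_z_x_gender"]],
               tolerance = 1e-10)
  expect_equal(suite$slope_men, cg[["score_z"]], tolerance = 1e-12)
})

test_that("site dummies are vacuous on a single-site cohort", {
  cfg <- synth_config(n_subjects = 40, site_sizes = 40L, prop_women = 0.5,
                      n_trials = 20, confidence_scale_dialect = "1-10",
                      seed = 23)
  coh <- simulate_cohort(cfg)
  m <- fdt_measures(coh$trials)
  suite <- run_measure_suite(m, coh$covariates, "threshold_filters",
                             "stai_state")
  expect_equal(suite$base$coefficients$estimate,
               suite$sensitivity_base$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("OLS matches a brute-force grid refinement on a two-parameter problem", {
  x <- 1:4
  y <- c(2, 4, 5, 8)
  sse <- function(a, b) sum((y - a - b * x)^2)
  ## iterative grid refinement around the best cell, independent of lm
  lo <- c(-5, -5); hi <- c(5, 5)
  for (round in 1:8) {
    as <- seq(lo[1], hi[1], length.out = 41)
    bs <- seq(lo[2], hi[2], length.out = 41)
    grid <- outer(as, bs, Vectorize(sse))
    ix <- which(grid == min(grid), arr.ind = TRUE)[1, ]
    step <- c(as[2] - as[1], bs[2] - bs[1])
    lo <- c(as[ix[1]], bs[ix[2]]) - step
    hi <- c(as[ix[1]], bs[ix[2]]) + step
  }
  best <- (lo + hi) / 2
  f <- fit_ols(y, cbind(x = x))
  expect_lt(abs(coef(f)[["intercept"]] - best[1]), 1e-4)
  expect_lt(abs(coef(f)[["x"]] - best[2]), 1e-4)
})
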