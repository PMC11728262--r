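## helper: a conf_counts object directly from cell counts
make_counts <- function(n_s1, n_s2) {
  structure(list(n_s1 = n_s1, n_s2 = n_s2, padded = FALSE, K = 10L),
            class = "conf_counts")
}

test_that("confidence down-sampling follows the 10-bin rule", {
  expect_equal(bin_confidence(7, "1-10"), 7L)
  expect_equal(bin_confidence(c(0, 100), "0-100"), c(1L, 10L))
  expect_equal(bin_confidence(55, "0-100"), 6L)
  expect_equal(bin_confidence(c(9, 10, 19, 20, 90), "0-100"),
               c(1L, 2L, 2L, 3L, 10L))
  ## monotone non-decreasing over the whole 0-100 dialect
  bins <- bin_confidence(0:100, "0-100")
  expect_true(all(diff(bins) >= 0))
  expect_error(bin_confidence(101, "0-100"), "confidence_out_of_range")
  expect_error(bin_confidence(0, "1-10"), "confidence_out_of_range")
})

test_that("threshold is the modal filter count, ties towards more filters", {
  tr <- function(f) data.frame(filter_count = f)
  expect_equal(estimate_threshold(tr(rep(3, 60))), 3L)
  expect_equal(estimate_threshold(tr(c(rep(4, 10), rep(3, 60)))), 3L)
  expect_equal(estimate_threshold(tr(c(rep(2, 30), rep(3, 30)))), 3L)
  expect_error(estimate_threshold(tr(integer(0))), "no trials")
})

test_that("type-1 estimates follow the z-transform formulas", {
  ## HR = 0.8, FAR = 0.2 with 100 trials per class
  cnt <- make_counts(c(rep(8, 10), rep(2, 10)), c(rep(2, 10), rep(8, 10)))
  est <- estimate_type1(cnt)
  expect_equal(est$hit_rate, 0.8)
  expect_equal(est$fa_rate, 0.2)
  expect_equal(est$d_prime, 2 * qnorm(0.8), tolerance = 1e-12)
  expect_equal(est$d_prime, 1.6832, tolerance = 1e-4)
  expect_equal(est$c, 0)
  expect_false(est$corrected)
  ## HR = FAR = 0.6: no sensitivity, a yes-bias
  cnt <- make_counts(c(rep(4, 10), rep(6, 10)), c(rep(4, 10), rep(6, 10)))
  est <- estimate_type1(cnt)
  expect_equal(est$d_prime, 0)
  expect_equal(est$c, qnorm(0.4), tolerance = 1e-12)
  expect_equal(est$c, -0.2533, tolerance = 1e-3)
  expect_lt(est$c, 0)
})

test_that("extreme rates are clamped by 1/(2N) so quantiles stay finite", {
  ## all 30 present trials answered yes, all 30 absent answered no
  cnt <- make_counts(c(rep(3, 10), rep(0, 10)), c(rep(0, 10), rep(3, 10)))
  est <- estimate_type1(cnt)
  expect_true(est$corrected)
  expect_equal(est$hit_rate, 1 - 1 / 60)
  expect_equal(est$fa_rate, 1 / 60)
  expect_true(is.finite(est$d_prime))
  ## a class with zero trials is an error
  cnt <- make_counts(rep(0, 20), c(rep(0, 10), rep(3, 10)))
  expect_error(estimate_type1(cnt), "both stimulus classes")
})

test_that("type-1 recovery from simulated counts at 50000 trials", {
  cfg <- synth_config(n_subjects = 1, site_sizes = 1L, prop_women = 0,
                      n_trials = 50000, d_prime_mean = 1.5, d_prime_sd = 0,
                      c_mean = -0.2, c_sd = 0, mu_logM = 0, sigma_logM = 0,
                      beta_anx_logM_men = 0, beta_anx_logM_women = 0,
                      confidence_scale_dialect = "1-10", seed = 22)
  m <- fdt_measures(simulate_cohort(cfg)$trials)
  expect_lt(abs(m$d_prime - 1.5), 0.02)
  expect_lt(abs(m$decision_bias + 0.2), 0.02)
})

test_that("metacognitive bias is the mean binned confidence over threshold trials", {
  tr <- data.frame(filter_count = c(3, 3, 3, 3, 4),
                   confidence_raw = c(2, 4, 6, 8, 10),
                   scale_dialect = "1-10")
  expect_equal(metacognitive_bias(tr, 3), 5)
  expect_equal(metacognitive_bias(data.frame(filter_count = 3,
                                             confidence_raw = 7,
                                             scale_dialect = "1-10"), 3), 7)
  ## 0-100 dialect subject: mean computed on binned values
  tr <- data.frame(filter_count = 2, confidence_raw = c(55, 100),
                   scale_dialect = "0-100")
  expect_equal(metacognitive_bias(tr, 2), 8)
  expect_error(metacognitive_bias(tr, 5), "threshold")
})

test_that("count construction conserves trials and places cells correctly", {
  tr <- data.frame(filter_count = 3, stimulus_present = 1L,
                   response_yes = 1L, confidence_raw = 10L,
                   scale_dialect = "1-10")
  cnt <- build_counts(tr, 3)
  expect_equal(sum(cnt$n_s2), 1)
  expect_equal(cnt$n_s2[20], 1)   # highest-confidence "yes" is the last cell
  expect_equal(sum(cnt$n_s1), 0)

  set.seed(31)
  tr <- data.frame(
    filter_count = 3,
    stimulus_present = rbinom(80, 1, 0.5),
    response_yes = rbinom(80, 1, 0.5),
    confidence_raw = sample(1:10, 80, replace = TRUE),
    scale_dialect = "1-10")
  cnt <- build_counts(tr, 3)
  expect_equal(sum(cnt$n_s1), sum(tr$stimulus_present == 0))
  expect_equal(sum(cnt$n_s2), sum(tr$stimulus_present == 1))
  ## round-trip: expand the counts back into trials and rebuild
  expand <- function(cnt) {
    rows <- list()
    for (stim in 0:1) {
      v <- if (stim == 0) cnt$n_s1 else cnt$n_s2
      for (cell in seq_along(v)) {
        if (v[cell] == 0) next
        resp <- as.integer(cell > 10)
        conf <- if (resp == 1) cell - 10L else 11L - cell
        rows[[length(rows) + 1L]] <- data.frame(
          filter_count = 3, stimulus_present = stim, response_yes = resp,
          confidence_raw = conf, scale_dialect = "1-10")[rep(1, v[cell]), ]
      }
    }
    do.call(rbind, rows)
  }
  cnt2 <- build_counts(expand(cnt), 3)
  expect_equal(cnt2$n_s1, cnt$n_s1)
  expect_equal(cnt2$n_s2, cnt$n_s2)
})

test_that("padding adds 1/(2K) to every cell only when zeros exist", {
  cnt <- make_counts(c(rep(0, 19), 5), c(rep(1, 20)))
  pad <- pad_counts(cnt)
  expect_true(pad$padded)
  expect_equal(pad$n_s1[1], 0.05)
  expect_equal(pad$n_s2[1], 1.05)
  full <- make_counts(rep(2, 20), rep(1, 20))
  expect_identical(pad_counts(full)$n_s1, full$n_s1)
})

test_that("fdt_measures assembles per-subject rows with attached counts", {
  cfg <- synth_config(n_subjects = 5, site_sizes = 5L, n_trials = 40,
                      confidence_scale_dialect = "1-10", seed = 13)
  coh <- simulate_cohort(cfg)
  m <- fdt_measures(coh$trials)
  expect_s3_class(m, "fdt_measures")
  expect_equal(nrow(m), 5)
  expect_true(all(m$metacog_bias >= 1 & m$metacog_bias <= 10))
  expect_true(all(m$threshold_filters >= 1))
  expect_length(attr(m, "counts"), 5)
  expect_error(fdt_measures(coh$trials[, -3]), "missing columns")
})
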