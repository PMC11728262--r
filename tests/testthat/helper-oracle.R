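## Independent oracles used by the tests. These deliberately re-derive the
## quantities from first principles rather than calling package internals.

## conditional type-2 log-likelihood of padded counts, written directly
## from the normal-area formulas; criteria given as absolute positions
oracle_type2_ll <- function(n_s1, n_s2, d, cc, meta_d, crit_no, crit_yes) {
  cpr <- cc * meta_d / d
  ll <- 0
  for (st in 1:2) {
    mu <- if (st == 1) -meta_d / 2 else meta_d / 2
    v <- if (st == 1) n_s1 else n_s2
    n_no <- rev(v[1:10])         # conf 1..10
    n_yes <- v[11:20]
    a_no <- pnorm(cpr - mu)
    edges <- c(cpr, crit_no)     # descending
    cum <- pnorm(edges - mu)
    p_no <- c(-diff(cum), cum[10]) / a_no
    edges <- c(cpr, crit_yes)    # ascending
    sf <- pnorm(edges - mu, lower.tail = FALSE)
    p_yes <- c(-diff(sf), sf[10]) / (1 - a_no)
    p <- c(p_no, p_yes); n <- c(n_no, n_yes)
    if (any(p <= 0 & n > 0)) return(-Inf)
    ll <- ll + sum(n[n > 0] * log(p[n > 0]))
  }
  ll
}

## one response side's conditional log-likelihood (factorizes over sides
## for fixed meta-d, so each side's criteria are optimized separately)
.oracle_side_ll <- function(n_no_or_yes, mus, a_resp, cpr, offs, side) {
  ll <- 0
  for (st in 1:2) {
    if (side == 1) {
      edges <- c(cpr, cpr - offs)
      cum <- pnorm(edges - mus[st])
      p <- c(-diff(cum), cum[10]) / a_resp[st]
    } else {
      edges <- c(cpr, cpr + offs)
      sf <- pnorm(edges - mus[st], lower.tail = FALSE)
      p <- c(-diff(sf), sf[10]) / a_resp[st]
    }
    n <- n_no_or_yes[, st]
    if (any(p <= 0 & n > 0)) return(-Inf)
    ll <- ll + sum(n[n > 0] * log(p[n > 0]))
  }
  ll
}

## exhaustive grid search over meta-d with nested criteria optimization,
## warm-started along the grid
oracle_grid_metad <- function(counts, d, cc,
                              grid = seq(0.05, 5, by = 0.005)) {
  counts <- pad_counts(counts)
  n_no <- cbind(rev(counts$n_s1[1:10]), rev(counts$n_s2[1:10]))
  n_yes <- cbind(counts$n_s1[11:20], counts$n_s2[11:20])
  side_fit <- function(par, meta_d, side) {
    cpr <- cc * meta_d / d
    mus <- c(-meta_d / 2, meta_d / 2)
    a_resp <- if (side == 1) pnorm(cpr - mus)
              else pnorm(cpr - mus, lower.tail = FALSE)
    nmat <- if (side == 1) n_no else n_yes
    optim(par, function(p)
      -.oracle_side_ll(nmat, mus, a_resp, cpr, cumsum(exp(p)), side),
      method = "BFGS", control = list(maxit = 200, reltol = 1e-10))
  }
  par_no <- par_yes <- rep(log(0.3), 9)
  best_ll <- -Inf; best_md <- grid[1]
  for (md in grid) {
    o1 <- side_fit(par_no, md, 1)
    o2 <- side_fit(par_yes, md, 2)
    par_no <- o1$par; par_yes <- o2$par
    ll <- -(o1$value + o2$value)
    if (ll > best_ll) { best_ll <- ll; best_md <- md }
  }
  list(meta_d = best_md, loglik = best_ll)
}

## random 60-trial count table from the equal-variance SDT generative model
random_count_table <- function(seed) {
  set.seed(seed)
  cfg <- synth_config(n_subjects = 1, site_sizes = 1L, prop_women = 0,
                      n_trials = 60,
                      d_prime_mean = runif(1, 0.8, 2), d_prime_sd = 0,
                      c_mean = runif(1, -0.3, 0.3), c_sd = 0,
                      mu_logM = runif(1, -0.5, 0.3), sigma_logM = 0,
                      beta_anx_logM_men = 0, beta_anx_logM_women = 0,
                      conf_baseline = 0, conf_bias_slope = 0,
                      conf_noise_sd = 0,
                      confidence_scale_dialect = "1-10", seed = seed)
  set.seed(seed)
  coh <- simulate_cohort(cfg)
  m <- fdt_measures(coh$trials)
  list(counts = attr(m, "counts")[[1]], d = m$d_prime[1],
       cc = m$decision_bias[1])
}
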