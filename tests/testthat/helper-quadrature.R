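## Exact-quadrature reference for the hierarchical model with the type-2
## criteria pinned to the anchored even partition (subject scales at 0)
## and type-1 parameters pinned. In that configuration each subject's
## likelihood is a 1-D function of logMratio, so the (mu, sigma)
## posterior is computable by brute-force integration, independently of
## the MCMC code.

## conditional type-2 log-likelihood, criteria = even partition of the
## span from cpr to -/+3 (at least 0.5), K = 10
quad_subj_ll <- function(cnt, d, cc, logM) {
  metad <- d * exp(logM)
  cpr <- cc * exp(logM)
  offN <- (1:9) / 10 * max(cpr + 3, 0.5)
  offY <- (1:9) / 10 * max(3 - cpr, 0.5)
  tot <- 0
  for (st in 1:2) {
    mu <- if (st == 1) -metad / 2 else metad / 2
    aNo <- pnorm(cpr - mu)
    edges <- c(cpr, cpr - offN)               # descending
    cum <- pnorm(edges - mu)
    pN <- c(-diff(cum), cum[10]) / aNo        # conf 1..10, "no"
    edges <- c(cpr, cpr + offY)
    sf <- pnorm(edges - mu, lower.tail = FALSE)
    pY <- c(-diff(sf), sf[10]) / (1 - aNo)    # conf 1..10, "yes"
    v <- if (st == 1) cnt$n_s1 else cnt$n_s2
    n <- c(rev(v[1:10]), v[11:20])
    p <- c(pN, pY)
    if (any(p <= 0 & n > 0)) return(-Inf)
    tot <- tot + sum(n[n > 0] * log(p[n > 0]))
  }
  tot
}

## posterior means of (mu, sigma) by 2-D grid integration
quad_posterior <- function(counts_list, d, cc,
                           grid_l = seq(-2, 1.2, by = 0.02),
                           mus = seq(-0.7, 0.4, by = 0.01),
                           sigs = seq(0.02, 0.7, by = 0.02)) {
  LL <- vapply(seq_along(counts_list), function(s)
    vapply(grid_l, function(l)
      quad_subj_ll(counts_list[[s]], d[s], cc[s], l), numeric(1)),
    numeric(length(grid_l)))
  LLs <- exp(sweep(LL, 2, apply(LL, 2, max)))
  lpost <- matrix(NA_real_, length(mus), length(sigs))
  for (i in seq_along(mus)) for (j in seq_along(sigs)) {
    w <- dnorm(grid_l, mus[i], sigs[j]) * (grid_l[2] - grid_l[1])
    fs <- colSums(LLs * w)
    lpost[i, j] <- sum(log(fs)) + dnorm(mus[i], 0, 1, log = TRUE) -
      0.5 * sigs[j]^2
  }
  p <- exp(lpost - max(lpost))
  c(mu = sum(p * mus) / sum(p), sigma = sum(t(p) * sigs) / sum(p))
}
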