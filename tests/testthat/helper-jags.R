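## Independent implementation of the hierarchical logMratio model in JAGS,
## used to cross-check the package's native sampler on small data sets.
## The multinomial uses constant smoothed response weights, which differs
## from the conditional type-2 likelihood only by an additive constant.

jags_hier_model <- "
model {
  mu ~ dnorm(0, 1)
  sigma ~ dnorm(0, 1) T(0,)
  tau <- pow(sigma, -2)
  tau_h ~ dnorm(0, 100) T(0,)
  prec_h <- pow(tau_h, -2)
  mu_ld ~ dnorm(0, 1)
  sig_ld ~ dnorm(0, 4) T(0,)
  mu_c ~ dnorm(0, 1)
  sig_c ~ dnorm(0, 4) T(0,)
  for (j in 1:9) { mgap[j] ~ dnorm(0, 0.444444) }
  G[1] <- exp(mgap[1])
  for (j in 2:9) { G[j] <- G[j-1] + exp(mgap[j]) }
  for (s in 1:N) {
    logM[s] ~ dnorm(mu, tau)
    ld[s] ~ dnorm(mu_ld, pow(sig_ld, -2))
    cc[s] ~ dnorm(mu_c, pow(sig_c, -2))
    hN[s] ~ dnorm(0, prec_h)
    hY[s] ~ dnorm(0, prec_h)
    d[s] <- exp(ld[s])
    metad[s] <- d[s] * exp(logM[s])
    cpr[s] <- cc[s] * exp(logM[s])
    scN[s] <- max(cpr[s] + 3, 0.5) / 10 * exp(hN[s])
    scY[s] <- max(3 - cpr[s], 0.5) / 10 * exp(hY[s])
    ## type-1 binomials
    yesA[s] ~ dbin(1 - phi(cc[s] + d[s] / 2), nA[s])
    yesP[s] ~ dbin(1 - phi(cc[s] - d[s] / 2), nP[s])
    ## type-2 cells
    for (st in 1:2) {
      mu2[s,st] <- ifelse(st == 1, -metad[s] / 2, metad[s] / 2)
      aN[s,st] <- phi(cpr[s] - mu2[s,st])
      pN[s,st,1] <- (phi(cpr[s]-mu2[s,st]) - phi(cpr[s]-scN[s]*G[1]-mu2[s,st])) / aN[s,st]
      for (k in 2:9) {
        pN[s,st,k] <- (phi(cpr[s]-scN[s]*G[k-1]-mu2[s,st]) -
                       phi(cpr[s]-scN[s]*G[k]-mu2[s,st])) / aN[s,st]
      }
      pN[s,st,10] <- phi(cpr[s]-scN[s]*G[9]-mu2[s,st]) / aN[s,st]
      pY[s,st,1] <- (phi(cpr[s]+scY[s]*G[1]-mu2[s,st]) - phi(cpr[s]-mu2[s,st])) / (1-aN[s,st])
      for (k in 2:9) {
        pY[s,st,k] <- (phi(cpr[s]+scY[s]*G[k]-mu2[s,st]) -
                       phi(cpr[s]+scY[s]*G[k-1]-mu2[s,st])) / (1-aN[s,st])
      }
      pY[s,st,10] <- (1 - phi(cpr[s]+scY[s]*G[9]-mu2[s,st])) / (1-aN[s,st])
    }
    for (k in 1:10) {
      pr1[s,k]    <- (1-w1[s]) * pN[s,1,k]
      pr1[s,k+10] <- w1[s] * pY[s,1,k]
      pr2[s,k]    <- (1-w2[s]) * pN[s,2,k]
      pr2[s,k+10] <- w2[s] * pY[s,2,k]
    }
    C1[s,1:20] ~ dmulti(pr1[s,1:20], n1[s])
    C2[s,1:20] ~ dmulti(pr2[s,1:20], n2[s])
  }
}
"

## run the JAGS reference on an fdt_measures object (no design)
jags_hier_reference <- function(measures, n_adapt = 1500, n_burn = 1500,
                                n_iter = 6000, seed = 1) {
  cnts <- attr(measures, "counts")
  ml <- function(v) c(rev(v[1:10]), v[11:20])
  C1 <- t(vapply(cnts, function(x) ml(x$n_s1), numeric(20)))
  C2 <- t(vapply(cnts, function(x) ml(x$n_s2), numeric(20)))
  N <- nrow(C1)
  dat <- list(
    N = N, C1 = C1, C2 = C2,
    n1 = rowSums(C1), n2 = rowSums(C2),
    w1 = (rowSums(C1[, 11:20, drop = FALSE]) + 0.5) / (rowSums(C1) + 1),
    w2 = (rowSums(C2[, 11:20, drop = FALSE]) + 0.5) / (rowSums(C2) + 1),
    yesA = rowSums(C1[, 11:20, drop = FALSE]),
    yesP = rowSums(C2[, 11:20, drop = FALSE]),
    nA = rowSums(C1), nP = rowSums(C2))
  inits <- list(mu = 0, sigma = 0.3, tau_h = 0.05, mu_ld = 0, sig_ld = 0.3,
                mu_c = 0, sig_c = 0.3, mgap = rep(0, 9),
                logM = rep(0, N), hN = rep(0, N), hY = rep(0, N),
                ld = log(pmax(measures$d_prime, 0.1)),
                cc = measures$decision_bias,
                .RNG.name = "base::Mersenne-Twister", .RNG.seed = seed)
  jm <- rjags::jags.model(textConnection(jags_hier_model), data = dat,
                          inits = inits, n.chains = 1, n.adapt = n_adapt,
                          quiet = TRUE)
  update(jm, n_burn, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("mu", "sigma"), n.iter = n_iter,
                           progress.bar = "none")
  colMeans(as.matrix(s[[1]]))
}
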