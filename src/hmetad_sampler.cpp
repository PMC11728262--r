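// Adaptive Metropolis-within-Gibbs sampler for the hierarchical meta-d'
// (logMratio) model with an optional subject-level covariate regression.
//
// Model (K confidence bins, N subjects):
//   logM_s   ~ Normal(mu + x_s' beta, sigma)
//   d_s, c_s ~ latent type-1 parameters with a binomial likelihood from
//              the subject's yes/no counts per stimulus (estimating them
//              inside the model instead of plugging in point estimates
//              removes the attenuation their sampling error causes in
//              logMratio at ~60 trials/subject)
//   metad_s  = d_s * exp(logM_s),  cpr_s = c_s * exp(logM_s)
//   type-2 criteria for subject s, response side v (no/yes):
//       cpr_s -/+ (range_v / K) * G_j * exp(h_{s,v})
//     where range_v is the evidence span from cpr to -/+3 (the scale a
//     rater can meaningfully partition), G_j = cumsum_j exp(m_j) is a
//     criterion-spacing *shape* learned from the whole group (G_j ~ j for
//     an even partition), and h_{s,v} ~ Normal(0, tau_h) is a tightly
//     shrunk per-subject, per-side log-scale. Free per-subject criteria
//     are deliberately avoided: with 10 confidence bins and ~60 trials
//     they are incidental parameters whose misplacement can only dilute
//     the confidence-accuracy coupling, which biases meta-d downward.
//   counts   ~ multinomial over confidence bins, conditional on
//     (stimulus, response); cell probabilities are normal areas between
//     adjacent criteria under evidence means -/+ metad/2.
// Priors: mu ~ N(0,1); beta_j ~ N(0,1); sigma ~ HalfNormal(1);
//         m_j ~ N(0, 1.5^2); tau_h ~ HalfNormal(0.1);
//         log d_s ~ N(mu_ld, sig_ld), c_s ~ N(mu_c, sig_c) with
//         mu_ld, mu_c ~ N(0,1) and sig_ld, sig_c ~ HalfNormal(0.5):
//         hierarchical shrinkage of the type-1 parameters tempers the
//         grid displacement their per-subject sampling error causes.
//
// The sticky direction of the posterior (sigma small, weak subject
// likelihoods) is handled by interweaving: after the centered updates,
// mu and sigma are re-updated under the non-centered parameterization
// (eta = (logM - mu - X beta)/sigma held fixed), which moves all subject
// logM values rigidly and decorrelates the hierarchy.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// shared shape: cumulative positive increments from log-increments m
static void shape_from_lg(const std::vector<double>& m,
                          std::vector<double>& G) {
  double acc = 0.0;
  for (size_t j = 0; j < m.size(); ++j) {
    acc += std::exp(m[j]);
    G[j] = acc;
  }
}

// conditional type-2 log-likelihood of one subject for one response side.
// scaleN/scaleY multiply the shared shape G to give criterion distances
// from cpr. side = 0: "no" responses (cells below cpr), 1: "yes".
// C is one subject's 2 x 2K count matrix (row 0 stimulus absent, row 1
// present); cols 0..K-1 "no" conf 1..K, K..2K-1 "yes" conf 1..K.
static double side_loglik(const IntegerMatrix& C, int K,
                          double metad, double cpr,
                          const std::vector<double>& G, double scale,
                          int side) {
  double ll = 0.0;
  for (int st = 0; st < 2; ++st) {
    double mu = (st == 0) ? -metad / 2.0 : metad / 2.0;
    double aNo = R::pnorm(cpr - mu, 0.0, 1.0, 1, 0);
    double denom = (side == 0) ? aNo : 1.0 - aNo;
    double prev = 0.0; // cumulative area from cpr outward
    for (int k = 1; k <= K; ++k) {
      int n = (side == 0) ? C(st, k - 1) : C(st, K + k - 1);
      double cum;
      if (k < K) {
        double off = scale * G[k - 1];
        double edge = (side == 0) ? cpr - off : cpr + off;
        if (side == 0)
          cum = aNo - R::pnorm(edge - mu, 0.0, 1.0, 1, 0);
        else
          cum = (1.0 - aNo) - R::pnorm(edge - mu, 0.0, 1.0, 0, 0);
      } else {
        cum = denom;
      }
      double p = (cum - prev) / denom;
      prev = cum;
      if (n > 0) {
        if (!(p > 0.0) || denom <= 0.0) return NEG_INF;
        ll += n * std::log(p);
      }
    }
  }
  return ll;
}

// per-side criterion scale: even partition of the span from cpr to -/+3
// (at least 0.5 wide), stretched by the subject's log-scale h
static inline double side_scale(double cpr, int side, double h, int K) {
  double range = (side == 0) ? std::max(cpr + 3.0, 0.5)
                             : std::max(3.0 - cpr, 0.5);
  return range / K * std::exp(h);
}

// type-1 binomial log-likelihood of the yes/no counts given (d, c);
// nA = (no, yes) counts for stimulus absent, nP likewise for present
static double type1_loglik(const int* nA, const int* nP, double d,
                           double c) {
  double pNoP = R::pnorm(c - d / 2.0, 0.0, 1.0, 1, 0); // P(no | present)
  double pNoA = R::pnorm(c + d / 2.0, 0.0, 1.0, 1, 0); // P(no | absent)
  double ll = 0.0;
  if (nP[0] > 0) { if (pNoP <= 0.0) return NEG_INF; ll += nP[0] * std::log(pNoP); }
  if (nP[1] > 0) { if (pNoP >= 1.0) return NEG_INF; ll += nP[1] * std::log(1.0 - pNoP); }
  if (nA[0] > 0) { if (pNoA <= 0.0) return NEG_INF; ll += nA[0] * std::log(pNoA); }
  if (nA[1] > 0) { if (pNoA >= 1.0) return NEG_INF; ll += nA[1] * std::log(1.0 - pNoA); }
  return ll;
}

static double subj_loglik(const IntegerMatrix& C, int K, double d1,
                          double c1, double logM,
                          const std::vector<double>& G,
                          double hN, double hY) {
  double metad = d1 * std::exp(logM);
  double cpr = c1 * std::exp(logM);
  double llN = side_loglik(C, K, metad, cpr, G, side_scale(cpr, 0, hN, K), 0);
  if (llN == NEG_INF) return NEG_INF;
  double llY = side_loglik(C, K, metad, cpr, G, side_scale(cpr, 1, hY, K), 1);
  if (llY == NEG_INF) return NEG_INF;
  return llN + llY;
}

// [[Rcpp::export(name = ".hmetad_sample_cpp")]]
List hmetad_sample_cpp(List counts, NumericVector d1, NumericVector c1,
                       NumericMatrix X, int n_burnin, int n_iter,
                       int K = 10,
                       Nullable<NumericVector> fix_shape = R_NilValue,
                       Nullable<NumericMatrix> fix_h = R_NilValue,
                       Nullable<NumericMatrix> fix_t1 = R_NilValue) {
  RNGScope scope;
  const int N = d1.size();
  const int P = X.ncol();
  const int Km1 = K - 1;
  const double M0 = 0.0, M0_SD = 1.5;  // shape log-increment prior

  std::vector<IntegerMatrix> C(N);
  for (int s = 0; s < N; ++s) C[s] = as<IntegerMatrix>(counts[s]);

  // per-subject type-1 response counts: (no, yes) x (absent, present)
  std::vector<std::array<int,2>> nT1A(N), nT1P(N);
  for (int s = 0; s < N; ++s) {
    int noA = 0, yesA = 0, noP = 0, yesP = 0;
    for (int k = 0; k < K; ++k) {
      noA += C[s](0, k); yesA += C[s](0, K + k);
      noP += C[s](1, k); yesP += C[s](1, K + k);
    }
    nT1A[s] = {noA, yesA};
    nT1P[s] = {noP, yesP};
  }

  // state
  std::vector<double> logM(N, 0.0), hN(N, 0.0), hY(N, 0.0);
  std::vector<double> ld(N), cc(N);     // latent type-1: log d, c
  for (int s = 0; s < N; ++s) {
    ld[s] = std::log(std::max(d1[s], 0.1));
    cc[s] = c1[s];
  }
  const bool t1_fixed = fix_t1.isNotNull();
  if (t1_fixed) {
    NumericMatrix ft(fix_t1);
    for (int s = 0; s < N; ++s) { ld[s] = ft(s, 0); cc[s] = ft(s, 1); }
  }
  std::vector<double> m_gap(Km1, M0);
  const bool shape_fixed = fix_shape.isNotNull();
  const bool h_fixed = fix_h.isNotNull();
  if (shape_fixed) {
    NumericVector fs(fix_shape);
    for (int j = 0; j < Km1; ++j) m_gap[j] = fs[j];
  }
  if (h_fixed) {
    NumericMatrix fh(fix_h);
    for (int s = 0; s < N; ++s) { hN[s] = fh(s, 0); hY[s] = fh(s, 1); }
  }
  double mu = 0.0, sigma = 0.3, tau_h = 0.05;
  double mu_ld = 0.0, sig_ld = 0.3, mu_c = 0.0, sig_c = 0.3;
  {
    double a = 0.0, b = 0.0;
    for (int s = 0; s < N; ++s) { a += ld[s]; b += cc[s]; }
    mu_ld = a / N; mu_c = b / N;
  }
  std::vector<double> beta(P, 0.0), xb(N, 0.0);

  std::vector<double> G(Km1), Gp(Km1);
  shape_from_lg(m_gap, G);

  // cached log-likelihoods per subject (type-2 conditional part; the
  // type-1 binomial part is cached separately)
  std::vector<double> ll(N), ll1(N);
  for (int s = 0; s < N; ++s) {
    ll[s] = subj_loglik(C[s], K, std::exp(ld[s]), cc[s], logM[s], G,
                        hN[s], hY[s]);
    ll1[s] = type1_loglik(nT1A[s].data(), nT1P[s].data(),
                          std::exp(ld[s]), cc[s]);
  }

  // adaptive proposal scales
  std::vector<double> s_logM(N, 0.3), s_hN(N, 0.15), s_hY(N, 0.15);
  std::vector<double> s_ld(N, 0.15), s_cc(N, 0.15);
  double s_sld = 0.2, s_scc = 0.2;
  double s_mu_nc = 0.05, s_sig_nc = 0.2, s_sig = 0.2, s_tau = 0.2;
  std::vector<double> s_mg(Km1, 0.08);
  const double tgt1 = 0.44;
  auto adapt = [](double& sc, bool acc, double tgt, int t) {
    double g = std::min(0.05, 1.0 / std::sqrt((double)t + 1.0));
    sc *= std::exp(g * ((acc ? 1.0 : 0.0) - tgt));
    if (sc < 1e-4) sc = 1e-4;
    if (sc > 10.0) sc = 10.0;
  };

  const int total = n_burnin + n_iter;
  NumericMatrix out(n_iter, 2 + P + N + Km1 + 1);
  std::vector<double> llp(N), lm(N);

  for (int t = 0; t < total; ++t) {
    bool adapting = t < n_burnin;

    // --- subject blocks -------------------------------------------------
    for (int s = 0; s < N; ++s) {
      double ds = std::exp(ld[s]);

      // logM random walk (type-1 part unaffected)
      double prop = logM[s] + R::norm_rand() * s_logM[s];
      double lp = subj_loglik(C[s], K, ds, cc[s], prop, G, hN[s], hY[s]);
      double lr = lp - ll[s] +
        R::dnorm(prop, mu + xb[s], sigma, 1) -
        R::dnorm(logM[s], mu + xb[s], sigma, 1);
      bool acc = std::log(unif_rand()) < lr;
      if (acc) { logM[s] = prop; ll[s] = lp; }
      if (adapting) adapt(s_logM[s], acc, tgt1, t);

      // latent type-1 d: random walk on log d
      if (!t1_fixed) {
      prop = ld[s] + R::norm_rand() * s_ld[s];
      {
        double lp2 = subj_loglik(C[s], K, std::exp(prop), cc[s], logM[s],
                                 G, hN[s], hY[s]);
        double lp1 = type1_loglik(nT1A[s].data(), nT1P[s].data(),
                                  std::exp(prop), cc[s]);
        double lr2 = lp2 - ll[s] + lp1 - ll1[s] +
          R::dnorm(prop, mu_ld, sig_ld, 1) -
          R::dnorm(ld[s], mu_ld, sig_ld, 1);
        acc = lp2 > NEG_INF && lp1 > NEG_INF &&
          std::log(unif_rand()) < lr2;
        if (acc) { ld[s] = prop; ll[s] = lp2; ll1[s] = lp1; }
        if (adapting) adapt(s_ld[s], acc, tgt1, t);
        ds = std::exp(ld[s]);
      }

      // latent type-1 c: random walk
      prop = cc[s] + R::norm_rand() * s_cc[s];
      {
        double lp2 = subj_loglik(C[s], K, ds, prop, logM[s], G,
                                 hN[s], hY[s]);
        double lp1 = type1_loglik(nT1A[s].data(), nT1P[s].data(), ds, prop);
        double lr2 = lp2 - ll[s] + lp1 - ll1[s] +
          R::dnorm(prop, mu_c, sig_c, 1) -
          R::dnorm(cc[s], mu_c, sig_c, 1);
        acc = lp2 > NEG_INF && lp1 > NEG_INF &&
          std::log(unif_rand()) < lr2;
        if (acc) { cc[s] = prop; ll[s] = lp2; ll1[s] = lp1; }
        if (adapting) adapt(s_cc[s], acc, tgt1, t);
      }

      }

      double metad = ds * std::exp(logM[s]);
      double cpr = cc[s] * std::exp(logM[s]);

      // "no"-side log-scale
      if (h_fixed) continue;
      prop = hN[s] + R::norm_rand() * s_hN[s];
      {
        double llN_new = side_loglik(C[s], K, metad, cpr, G,
                                     side_scale(cpr, 0, prop, K), 0);
        double llN_old = side_loglik(C[s], K, metad, cpr, G,
                                     side_scale(cpr, 0, hN[s], K), 0);
        double lr2 = llN_new - llN_old +
          R::dnorm(prop, 0.0, tau_h, 1) - R::dnorm(hN[s], 0.0, tau_h, 1);
        acc = llN_new > NEG_INF && std::log(unif_rand()) < lr2;
        if (acc) { hN[s] = prop; ll[s] += llN_new - llN_old; }
        if (adapting) adapt(s_hN[s], acc, tgt1, t);
      }

      // "yes"-side log-scale
      prop = hY[s] + R::norm_rand() * s_hY[s];
      {
        double llY_new = side_loglik(C[s], K, metad, cpr, G,
                                     side_scale(cpr, 1, prop, K), 1);
        double llY_old = side_loglik(C[s], K, metad, cpr, G,
                                     side_scale(cpr, 1, hY[s], K), 1);
        double lr2 = llY_new - llY_old +
          R::dnorm(prop, 0.0, tau_h, 1) - R::dnorm(hY[s], 0.0, tau_h, 1);
        acc = llY_new > NEG_INF && std::log(unif_rand()) < lr2;
        if (acc) { hY[s] = prop; ll[s] += llY_new - llY_old; }
        if (adapting) adapt(s_hY[s], acc, tgt1, t);
      }
    }

    // --- mu: conjugate Gibbs (prior N(0,1)) -----------------------------
    {
      double sum = 0.0;
      for (int s = 0; s < N; ++s) sum += logM[s] - xb[s];
      double prec = N / (sigma * sigma) + 1.0;
      double mean = (sum / (sigma * sigma)) / prec;
      mu = mean + R::norm_rand() / std::sqrt(prec);
    }

    // --- beta: conjugate Gibbs (prior N(0, I)) --------------------------
    if (P > 0) {
      std::vector<double> A(P * P, 0.0), b(P, 0.0);
      double is2 = 1.0 / (sigma * sigma);
      for (int s = 0; s < N; ++s) {
        double r = logM[s] - mu;
        for (int i = 0; i < P; ++i) {
          b[i] += X(s, i) * r * is2;
          for (int j = 0; j <= i; ++j)
            A[i * P + j] += X(s, i) * X(s, j) * is2;
        }
      }
      for (int i = 0; i < P; ++i) A[i * P + i] += 1.0;
      std::vector<double> L(P * P, 0.0);
      for (int i = 0; i < P; ++i)
        for (int j = 0; j <= i; ++j) {
          double sum = A[i * P + j];
          for (int k = 0; k < j; ++k) sum -= L[i * P + k] * L[j * P + k];
          if (i == j) L[i * P + i] = std::sqrt(sum);
          else L[i * P + j] = sum / L[j * P + j];
        }
      std::vector<double> y(P), m(P);
      for (int i = 0; i < P; ++i) {
        double sum = b[i];
        for (int k = 0; k < i; ++k) sum -= L[i * P + k] * y[k];
        y[i] = sum / L[i * P + i];
      }
      for (int i = P - 1; i >= 0; --i) {
        double sum = y[i];
        for (int k = i + 1; k < P; ++k) sum -= L[k * P + i] * m[k];
        m[i] = sum / L[i * P + i];
      }
      // draw: solve L' v = z, then beta = m + v
      std::vector<double> z(P), v(P);
      for (int i = 0; i < P; ++i) z[i] = R::norm_rand();
      for (int i = P - 1; i >= 0; --i) {
        double sum = z[i];
        for (int k = i + 1; k < P; ++k) sum -= L[k * P + i] * v[k];
        v[i] = sum / L[i * P + i];
      }
      for (int i = 0; i < P; ++i) beta[i] = m[i] + v[i];
      for (int s = 0; s < N; ++s) {
        double v = 0.0;
        for (int j = 0; j < P; ++j) v += X(s, j) * beta[j];
        xb[s] = v;
      }
    }

    // --- sigma: centered random walk on log sigma -----------------------
    {
      double lsig = std::log(sigma);
      double prop = lsig + R::norm_rand() * s_sig;
      double sp = std::exp(prop);
      double lr = 0.0;
      for (int s = 0; s < N; ++s)
        lr += R::dnorm(logM[s], mu + xb[s], sp, 1) -
              R::dnorm(logM[s], mu + xb[s], sigma, 1);
      // HalfNormal(1) prior + log-Jacobian of the log transform
      lr += (-0.5 * sp * sp + prop) - (-0.5 * sigma * sigma + lsig);
      bool acc = std::log(unif_rand()) < lr;
      if (acc) sigma = sp;
      if (adapting) adapt(s_sig, acc, tgt1, t);
    }

    // --- interweaving (non-centered) updates of mu and sigma ------------
    {
      std::vector<double> eta(N);
      for (int s = 0; s < N; ++s) eta[s] = (logM[s] - mu - xb[s]) / sigma;

      // mu shift: logM' = logM + (mu' - mu)
      double prop = mu + R::norm_rand() * s_mu_nc;
      double delta = prop - mu;
      double lr = R::dnorm(prop, 0.0, 1.0, 1) - R::dnorm(mu, 0.0, 1.0, 1);
      for (int s = 0; s < N; ++s) {
        llp[s] = subj_loglik(C[s], K, std::exp(ld[s]), cc[s],
                             logM[s] + delta, G, hN[s], hY[s]);
        if (llp[s] == NEG_INF) { lr = NEG_INF; break; }
        lr += llp[s] - ll[s];
      }
      bool acc = lr > NEG_INF && std::log(unif_rand()) < lr;
      if (acc) {
        mu = prop;
        for (int s = 0; s < N; ++s) { logM[s] += delta; ll[s] = llp[s]; }
      }
      if (adapting) adapt(s_mu_nc, acc, tgt1, t);

      // sigma scale: logM' = mu + xb + sigma' * eta
      double lsig = std::log(sigma);
      double lprop = lsig + R::norm_rand() * s_sig_nc;
      double sp = std::exp(lprop);
      lr = (-0.5 * sp * sp + lprop) - (-0.5 * sigma * sigma + lsig);
      for (int s = 0; s < N; ++s) {
        lm[s] = mu + xb[s] + sp * eta[s];
        llp[s] = subj_loglik(C[s], K, std::exp(ld[s]), cc[s], lm[s], G,
                             hN[s], hY[s]);
        if (llp[s] == NEG_INF) { lr = NEG_INF; break; }
        lr += llp[s] - ll[s];
      }
      acc = lr > NEG_INF && std::log(unif_rand()) < lr;
      if (acc) {
        sigma = sp;
        for (int s = 0; s < N; ++s) { logM[s] = lm[s]; ll[s] = llp[s]; }
      }
      if (adapting) adapt(s_sig_nc, acc, tgt1, t);
    }

    // --- shared criterion shape: one coordinate per sweep ---------------
    if (!shape_fixed) {
      int j = (int)std::floor(unif_rand() * Km1);
      if (j >= Km1) j = Km1 - 1;
      double old_mj = m_gap[j];
      double prop = old_mj + R::norm_rand() * s_mg[j];
      double lr = R::dnorm(prop, M0, M0_SD, 1) -
                  R::dnorm(old_mj, M0, M0_SD, 1);
      m_gap[j] = prop;
      shape_from_lg(m_gap, Gp);
      for (int s = 0; s < N; ++s) {
        llp[s] = subj_loglik(C[s], K, std::exp(ld[s]), cc[s], logM[s], Gp,
                             hN[s], hY[s]);
        if (llp[s] == NEG_INF) { lr = NEG_INF; break; }
        lr += llp[s] - ll[s];
      }
      bool acc = lr > NEG_INF && std::log(unif_rand()) < lr;
      if (acc) {
        G = Gp;
        for (int s = 0; s < N; ++s) ll[s] = llp[s];
      } else {
        m_gap[j] = old_mj;
      }
      if (adapting) adapt(s_mg[j], acc, tgt1, t);
    }

    // --- type-1 population hyper-parameters -----------------------------
    if (!t1_fixed) {
      // means: conjugate normal-normal Gibbs, prior N(0,1)
      double a = 0.0, b = 0.0;
      for (int s = 0; s < N; ++s) { a += ld[s]; b += cc[s]; }
      double prec = N / (sig_ld * sig_ld) + 1.0;
      mu_ld = (a / (sig_ld * sig_ld)) / prec +
              R::norm_rand() / std::sqrt(prec);
      prec = N / (sig_c * sig_c) + 1.0;
      mu_c = (b / (sig_c * sig_c)) / prec +
             R::norm_rand() / std::sqrt(prec);
      // scales: random walk on log, HalfNormal(0.5) prior
      for (int which = 0; which < 2; ++which) {
        double& sg = (which == 0) ? sig_ld : sig_c;
        double& sc = (which == 0) ? s_sld : s_scc;
        double m0 = (which == 0) ? mu_ld : mu_c;
        const std::vector<double>& v = (which == 0) ? ld : cc;
        double lsd = std::log(sg);
        double lprop = lsd + R::norm_rand() * sc;
        double sp = std::exp(lprop);
        double lr = (-2.0 * sp * sp + lprop) - (-2.0 * sg * sg + lsd);
        for (int s = 0; s < N; ++s)
          lr += R::dnorm(v[s], m0, sp, 1) - R::dnorm(v[s], m0, sg, 1);
        bool acc = std::log(unif_rand()) < lr;
        if (acc) sg = sp;
        if (adapting) adapt(sc, acc, tgt1, t);
      }
    }

    // --- tau_h: random walk on log, HalfNormal(0.1) prior ---------------
    if (!h_fixed) {
      double ltau = std::log(tau_h);
      double lprop = ltau + R::norm_rand() * s_tau;
      double tp = std::exp(lprop);
      double lr = (-50.0 * tp * tp + lprop) - (-50.0 * tau_h * tau_h + ltau);
      for (int s = 0; s < N; ++s)
        lr += R::dnorm(hN[s], 0.0, tp, 1) - R::dnorm(hN[s], 0.0, tau_h, 1) +
              R::dnorm(hY[s], 0.0, tp, 1) - R::dnorm(hY[s], 0.0, tau_h, 1);
      bool acc = std::log(unif_rand()) < lr;
      if (acc) tau_h = tp;
      if (adapting) adapt(s_tau, acc, tgt1, t);
    }

    // --- record ----------------------------------------------------------
    if (t >= n_burnin) {
      int r = t - n_burnin;
      int col = 0;
      out(r, col++) = mu;
      out(r, col++) = sigma;
      for (int j = 0; j < P; ++j) out(r, col++) = beta[j];
      for (int s = 0; s < N; ++s) out(r, col++) = logM[s];
      for (int j = 0; j < Km1; ++j) out(r, col++) = m_gap[j];
      out(r, col++) = tau_h;
    }
  }

  return List::create(_["draws"] = out);
}
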