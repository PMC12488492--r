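// MCMC core for module-structured gLV inference.
//
// One Gibbs sweep updates, in order: (a) latent log-trajectories
// (per-site Metropolis-Hastings), (b) growth / self-interaction /
// interaction / perturbation coefficients (conjugate Gaussian, truncated
// where positivity is required), (c) spike-and-slab indicators (coefficient
// marginalized out in closed form, collapsed Beta-Bernoulli prior),
// (d) module assignments (auxiliary-variable Gibbs in the style of Neal's
// algorithm 8, with prior-drawn parameters for a candidate new module),
// (e) process variance (conjugate inverse-Gamma) and (f) the DP
// concentration (Escobar-West auxiliary-variable update).
//
// All randomness goes through R's RNG so runs are reproducible via
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Subj {
  arma::mat Y;            // n x K counts
  arma::vec r;            // K read depths
  arma::vec qn, qmean, qvar; // qPCR replicate count, mean-log, var per sample
  arma::vec delta;        // K-1 time gaps
  arma::mat H;            // P x K perturbation activity
  int K;
};

struct Model {
  int n, S, P;
  double d0, d1, relfloor;
  std::vector<Subj> subs;
  double m_a1, v_a1, m_a2, v_a2, v_b, v_g;
  double w_shape, w_rate, a_shape, a_rate;
  double zb_a, zb_b, zg_a, zg_b;
  double x0_m, x0_v;   // lognormal prior on initial latent states
};

struct State {
  std::vector<arma::mat> logX, X; // n x K each
  arma::vec a1, a2;
  arma::ivec c;                   // 0-based module labels
  arma::mat b;  arma::imat zb;    // M x M
  arma::mat gam; arma::imat zg;   // P x M
  double sw2, alpha;
  int M;
  arma::vec prop_sd;              // per-taxon latent proposal sd
  std::vector<arma::mat> Smod;    // M x K module sums
  std::vector<arma::vec> Tot;     // K totals
};

static void rebuild_caches(const Model& mo, State& st) {
  st.Smod.assign(mo.S, arma::mat());
  st.Tot.assign(mo.S, arma::vec());
  for (int s = 0; s < mo.S; s++) {
    st.X[s] = arma::exp(st.logX[s]);
    int K = mo.subs[s].K;
    st.Smod[s].zeros(st.M, K);
    for (int i = 0; i < mo.n; i++) st.Smod[s].row(st.c[i]) += st.X[s].row(i);
    st.Tot[s] = arma::sum(st.X[s], 0).t();
  }
}

static double nb_ll(double y, double mu, double eps) {
  if (eps < 1e-12) return R::dpois(y, mu, 1);
  double size = 1.0 / eps;
  return R::lgammafn(y + size) - R::lgammafn(size) - R::lgammafn(y + 1.0)
       + size * std::log(size / (size + mu)) + y * std::log(mu / (size + mu));
}

// truncated normal on [lower, inf)
static double rtnorm_lower(double mean, double sd, double lower) {
  double a = (lower - mean) / sd;
  if (a < 0.5) {
    for (int it = 0; it < 1000; it++) {
      double z = R::norm_rand();
      if (z >= a) return mean + sd * z;
    }
  }
  double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
  while (true) {
    double z = a + R::exp_rand() / lam;
    if (R::unif_rand() < std::exp(-0.5 * (z - lam) * (z - lam)))
      return mean + sd * z;
  }
}

// drift bracket F_j(k) for subject s given current caches
static double Fval(const Model& mo, const State& st, int s, int j, int k) {
  const Subj& D = mo.subs[s];
  int cj = st.c[j];
  double g = 1.0;
  for (int p = 0; p < mo.P; p++)
    if (st.zg(p, cj)) g += st.gam(p, cj) * D.H(p, k);
  double F = st.a1[j] * g - st.a2[j] * st.X[s](j, k);
  for (int m = 0; m < st.M; m++)
    if (m != cj && st.zb(cj, m)) F += st.b(cj, m) * st.Smod[s](m, k);
  return F;
}

static double growth_mod(const Model& mo, const State& st, int s, int j, int k) {
  int cj = st.c[j];
  double g = 1.0;
  for (int p = 0; p < mo.P; p++)
    if (st.zg(p, cj)) g += st.gam(p, cj) * mo.subs[s].H(p, k);
  return g;
}

// emission log-likelihood at (s, k) with taxon i's abundance overridden
static double emis_ll(const Model& mo, const State& st, int s, int k,
                      int i_over, double xi, double T) {
  const Subj& D = mo.subs[s];
  double ll = 0.0;
  for (int j = 0; j < mo.n; j++) {
    double xj = (j == i_over) ? xi : st.X[s](j, k);
    double rel = xj / T;
    double mu = D.r[k] * rel;
    double eps = mo.d0 / std::max(rel, mo.relfloor) + mo.d1;
    ll += nb_ll(D.Y(j, k), mu, eps);
  }
  if (D.qn[k] > 0) {
    double dv = D.qmean[k] - std::log(T);
    ll += -D.qn[k] * dv * dv / (2.0 * D.qvar[k]);
  }
  return ll;
}

// ---------------------------------------------------------------- latents
static void update_latents(const Model& mo, State& st,
                           arma::vec& acc, arma::vec& tries) {
  for (int s = 0; s < mo.S; s++) {
    const Subj& D = mo.subs[s];
    int K = D.K;
    for (int i = 0; i < mo.n; i++) {
      int ci = st.c[i];
      for (int k = 0; k < K; k++) {
        double lx_old = st.logX[s](i, k), x_old = st.X[s](i, k);
        double lx_new = lx_old + st.prop_sd[i] * R::norm_rand();
        tries[i] += 1.0;
        if (lx_new > 80.0 || lx_new < -80.0) continue;
        double x_new = std::exp(lx_new);
        double Tnew = st.Tot[s][k] - x_old + x_new;
        double dS = x_new - x_old;
        double dll = 0.0;
        if (k == 0) {
          dll += (-(lx_new - mo.x0_m) * (lx_new - mo.x0_m)
                  + (lx_old - mo.x0_m) * (lx_old - mo.x0_m)) / (2.0 * mo.x0_v);
        }
        if (k > 0) {
          double lmu = st.logX[s](i, k - 1) + D.delta[k - 1] * Fval(mo, st, s, i, k - 1);
          double v = D.delta[k - 1] * st.sw2;
          dll += (-(lx_new - lmu) * (lx_new - lmu)
                  + (lx_old - lmu) * (lx_old - lmu)) / (2.0 * v);
        }
        if (k < K - 1) {
          double v = D.delta[k] * st.sw2;
          for (int j = 0; j < mo.n; j++) {
            int cj = st.c[j];
            bool aff = (j == i) || (cj != ci && st.zb(cj, ci) && st.b(cj, ci) != 0.0);
            if (!aff) continue;
            double Fcur = Fval(mo, st, s, j, k);
            double Fnew, lx_j = st.logX[s](j, k);
            if (j == i) {
              Fnew = Fcur - st.a2[i] * (x_new - x_old);
              lx_j = lx_new;
            } else {
              Fnew = Fcur + st.b(cj, ci) * dS;
            }
            double lmu_cur = st.logX[s](j, k) + D.delta[k] * Fcur;
            double lmu_new = lx_j + D.delta[k] * Fnew;
            double e_cur = st.logX[s](j, k + 1) - lmu_cur;
            double e_new = st.logX[s](j, k + 1) - lmu_new;
            dll += (-e_new * e_new + e_cur * e_cur) / (2.0 * v);
          }
        }
        dll += emis_ll(mo, st, s, k, i, x_new, Tnew)
             - emis_ll(mo, st, s, k, -1, 0.0, st.Tot[s][k]);
        if (std::log(R::unif_rand()) < dll) {
          st.logX[s](i, k) = lx_new;
          st.X[s](i, k) = x_new;
          st.Tot[s][k] = Tnew;
          st.Smod[s](ci, k) += dS;
          acc[i] += 1.0;
        }
      }
    }
  }
}

// ------------------------------------------------------------ coefficients
// Accumulate precision/rhs for a linear coefficient with residuals taken
// over rows (taxa) in `rows`; `reg_kind` selects the regressor:
// 0: growth modifier (for a1), 1: -x_i (for a2), 2: Smod[mp] (for b),
// 3: a1_i * H[p] (for gamma). The focal term is removed from F via
// `coef * reg` so e = D - F + coef*reg.
struct LinStat { double prec_add = 0.0, rhs = 0.0; };

static LinStat lin_stats(const Model& mo, const State& st,
                         const std::vector<int>& rows, int reg_kind,
                         int mp, int p, double coef) {
  LinStat out;
  for (int s = 0; s < mo.S; s++) {
    const Subj& D = mo.subs[s];
    for (size_t ri = 0; ri < rows.size(); ri++) {
      int i = rows[ri];
      for (int k = 0; k < D.K - 1; k++) {
        double reg;
        switch (reg_kind) {
          case 0: reg = growth_mod(mo, st, s, i, k); break;
          case 1: reg = -st.X[s](i, k); break;
          case 2: reg = st.Smod[s](mp, k); break;
          default: reg = st.a1[i] * D.H(p, k); break;
        }
        if (reg == 0.0) continue;
        double w = D.delta[k] / st.sw2;
        double Dk = (st.logX[s](i, k + 1) - st.logX[s](i, k)) / D.delta[k];
        double e = Dk - Fval(mo, st, s, i, k) + coef * reg;
        out.prec_add += w * reg * reg;
        out.rhs += w * reg * e;
      }
    }
  }
  return out;
}

static void update_coefficients(const Model& mo, State& st) {
  std::vector< std::vector<int> > members(st.M);
  for (int i = 0; i < mo.n; i++) members[st.c[i]].push_back(i);

  for (int i = 0; i < mo.n; i++) {
    std::vector<int> rows(1, i);
    // growth a1_i > 0
    LinStat sgr = lin_stats(mo, st, rows, 0, 0, 0, st.a1[i]);
    double prec = 1.0 / mo.v_a1 + sgr.prec_add;
    double mean = (mo.m_a1 / mo.v_a1 + sgr.rhs) / prec;
    st.a1[i] = rtnorm_lower(mean, 1.0 / std::sqrt(prec), 0.0);
    // self-interaction a2_i >= 0
    LinStat ssi = lin_stats(mo, st, rows, 1, 0, 0, st.a2[i]);
    prec = 1.0 / mo.v_a2 + ssi.prec_add;
    mean = (mo.m_a2 / mo.v_a2 + ssi.rhs) / prec;
    st.a2[i] = rtnorm_lower(mean, 1.0 / std::sqrt(prec), 0.0);
  }
  for (int m = 0; m < st.M; m++) {
    for (int mp = 0; mp < st.M; mp++) {
      if (m == mp) continue;
      if (st.zb(m, mp)) {
        double coef = st.b(m, mp);
        LinStat sb = lin_stats(mo, st, members[m], 2, mp, 0, coef);
        double prec = 1.0 / mo.v_b + sb.prec_add;
        double mean = sb.rhs / prec;
        st.b(m, mp) = R::rnorm(mean, 1.0 / std::sqrt(prec));
      } else {
        st.b(m, mp) = R::rnorm(0.0, std::sqrt(mo.v_b));
      }
    }
  }
  for (int p = 0; p < mo.P; p++) {
    for (int m = 0; m < st.M; m++) {
      if (st.zg(p, m)) {
        double coef = st.gam(p, m);
        LinStat sg = lin_stats(mo, st, members[m], 3, 0, p, coef);
        double prec = 1.0 / mo.v_g + sg.prec_add;
        double mean = sg.rhs / prec;
        st.gam(p, m) = R::rnorm(mean, 1.0 / std::sqrt(prec));
      } else {
        st.gam(p, m) = R::rnorm(0.0, std::sqrt(mo.v_g));
      }
    }
  }
}

// ------------------------------------------------------------- indicators
// Collapsed Beta-Bernoulli prior inclusion probability for one entry given
// the others (Polya urn): (a + k_others) / (a + b + n_total - 1).
static double bb_cond_p(double a, double bpar, int k_others, int n_total) {
  return (a + k_others) / (a + bpar + n_total - 1.0);
}

static void update_indicators(const Model& mo, State& st,
                              bool do_b, bool do_g) {
  std::vector< std::vector<int> > members(st.M);
  for (int i = 0; i < mo.n; i++) members[st.c[i]].push_back(i);
  int M = st.M;
  int ntot_b = M * (M - 1);

  if (do_b && ntot_b > 0) {
    for (int m = 0; m < M; m++) {
      for (int mp = 0; mp < M; mp++) {
        if (m == mp) continue;
        double coef = st.zb(m, mp) ? st.b(m, mp) : 0.0;
        LinStat sb = lin_stats(mo, st, members[m], 2, mp, 0, coef);
        double Sw = sb.prec_add, h = sb.rhs;
        double lml = -0.5 * std::log1p(mo.v_b * Sw)
                   + 0.5 * mo.v_b * h * h / (1.0 + mo.v_b * Sw);
        int k_others = arma::accu(st.zb) - st.zb(m, mp);
        double p1 = bb_cond_p(mo.zb_a, mo.zb_b, k_others, ntot_b);
        double logit = lml + std::log(p1) - std::log1p(-p1);
        double pr = 1.0 / (1.0 + std::exp(-logit));
        st.zb(m, mp) = (R::unif_rand() < pr) ? 1 : 0;
        if (st.zb(m, mp)) {
          double prec = 1.0 / mo.v_b + Sw;
          st.b(m, mp) = R::rnorm(h / prec, 1.0 / std::sqrt(prec));
        } else {
          st.b(m, mp) = R::rnorm(0.0, std::sqrt(mo.v_b));
        }
      }
    }
  }
  if (!do_g) return;
  int ntot_g = mo.P * M;
  for (int p = 0; p < mo.P; p++) {
    for (int m = 0; m < M; m++) {
      double coef = st.zg(p, m) ? st.gam(p, m) : 0.0;
      LinStat sg = lin_stats(mo, st, members[m], 3, 0, p, coef);
      double Sw = sg.prec_add, h = sg.rhs;
      double lml = -0.5 * std::log1p(mo.v_g * Sw)
                 + 0.5 * mo.v_g * h * h / (1.0 + mo.v_g * Sw);
      int k_others = arma::accu(st.zg) - st.zg(p, m);
      double p1 = bb_cond_p(mo.zg_a, mo.zg_b, k_others, ntot_g);
      double logit = lml + std::log(p1) - std::log1p(-p1);
      double pr = 1.0 / (1.0 + std::exp(-logit));
      st.zg(p, m) = (R::unif_rand() < pr) ? 1 : 0;
      if (st.zg(p, m)) {
        double prec = 1.0 / mo.v_g + Sw;
        st.gam(p, m) = R::rnorm(h / prec, 1.0 / std::sqrt(prec));
      } else {
        st.gam(p, m) = R::rnorm(0.0, std::sqrt(mo.v_g));
      }
    }
  }
}

// ----------------------------------------------------------------- modules
// Collapsed evidence for one target-module block under a candidate
// assignment. Conditional on the indicators, growth/self-interaction,
// process variance and latents, the interaction and perturbation
// coefficients enter the transition means linearly and are integrated out
// in closed form. The joint evidence factorizes over target modules m
// (the coefficients b[m, .] and gamma[., m] only touch residuals of taxa
// in m), and the residuals e_jk = D_jk - a1_j + a2_j x_j(k) do not depend
// on the assignment, so their quadratic term cancels across candidates
// and is dropped.
//
// Block evidence (up to that constant):
//   -0.5 log det(I + V0 L) + 0.5 h' (V0^-1 + L)^-1 h
// with L = G'WG and h = G'We accumulated from module-sum and
// perturbation regressors.
static double block_evidence(const Model& mo, const State& st, int m,
                             int cand, int i_mov, int Mtot,
                             const std::vector<arma::mat>& Sbase,
                             const std::vector<arma::mat>& E) {
  // active columns: interactions into m, perturbations of m
  std::vector<int> bcols, gcols;
  for (int mp = 0; mp < Mtot; mp++)
    if (mp != m && st.zb(m, mp)) bcols.push_back(mp);
  for (int p = 0; p < mo.P; p++)
    if (st.zg(p, m)) gcols.push_back(p);
  int qb = bcols.size(), qg = gcols.size(), q = qb + qg;
  if (q == 0) return 0.0;

  // membership aggregates under the candidate assignment
  double nm = 0.0, A1 = 0.0, A2 = 0.0;
  for (int j = 0; j < mo.n; j++) {
    int cj = (j == i_mov) ? cand : st.c[j];
    if (cj != m) continue;
    nm += 1.0; A1 += st.a1[j]; A2 += st.a1[j] * st.a1[j];
  }
  if (nm == 0.0) return 0.0;

  arma::mat L(q, q, arma::fill::zeros);
  arma::vec h(q, arma::fill::zeros);
  for (int s = 0; s < mo.S; s++) {
    const Subj& D = mo.subs[s];
    for (int k = 0; k < D.K - 1; k++) {
      double w = D.delta[k] / st.sw2;
      // candidate-adjusted module sums and residual aggregates
      double Em = 0.0, EAm = 0.0;
      for (int j = 0; j < mo.n; j++) {
        int cj = (j == i_mov) ? cand : st.c[j];
        if (cj != m) continue;
        Em += E[s](j, k);
        EAm += st.a1[j] * E[s](j, k);
      }
      for (int u = 0; u < qb; u++) {
        double Su = Sbase[s](bcols[u], k) +
          ((bcols[u] == cand) ? st.X[s](i_mov, k) : 0.0);
        for (int v = u; v < qb; v++) {
          double Sv = Sbase[s](bcols[v], k) +
            ((bcols[v] == cand) ? st.X[s](i_mov, k) : 0.0);
          L(u, v) += nm * w * Su * Sv;
        }
        for (int v = 0; v < qg; v++) {
          L(u, qb + v) += A1 * w * Su * D.H(gcols[v], k);
        }
        h[u] += w * Su * Em;
      }
      for (int u = 0; u < qg; u++) {
        for (int v = u; v < qg; v++) {
          L(qb + u, qb + v) += A2 * w * D.H(gcols[u], k) * D.H(gcols[v], k);
        }
        h[qb + u] += w * D.H(gcols[u], k) * EAm;
      }
    }
  }
  L = arma::symmatu(L);
  arma::vec v0(q);
  for (int u = 0; u < qb; u++) v0[u] = mo.v_b;
  for (int u = 0; u < qg; u++) v0[qb + u] = mo.v_g;
  // rescale to unit prior variance per column; the evidence is invariant
  // but the linear systems become well conditioned despite the huge
  // dynamic range between abundance-sum and perturbation regressors
  arma::vec sc = arma::sqrt(v0);
  arma::mat Ls = L;
  for (int u = 0; u < q; u++)
    for (int v = 0; v < q; v++) Ls(u, v) *= sc[u] * sc[v];
  arma::vec hs = h % sc;
  arma::mat P = arma::eye(q, q) + Ls;
  double ld, sgn;
  arma::log_det(ld, sgn, P);
  arma::vec sol = arma::solve(P, hs, arma::solve_opts::likely_sympd);
  return -0.5 * ld + 0.5 * arma::dot(hs, sol);
}

static void shed_module(State& st, int m) {
  st.b.shed_row(m);  st.b.shed_col(m);
  st.zb.shed_row(m); st.zb.shed_col(m);
  if (st.gam.n_rows > 0) { st.gam.shed_col(m); st.zg.shed_col(m); }
  else { st.gam.set_size(0, st.M - 1); st.zg.set_size(0, st.M - 1); }
  for (unsigned int i = 0; i < st.c.n_elem; i++)
    if (st.c[i] > m) st.c[i]--;
  st.M--;
}

static void update_modules(const Model& mo, State& st) {
  // residuals without interaction/perturbation terms; independent of the
  // module assignment being resampled
  std::vector<arma::mat> E(mo.S);
  for (int s = 0; s < mo.S; s++) {
    const Subj& D = mo.subs[s];
    E[s].zeros(mo.n, std::max(D.K - 1, 1));
    for (int j = 0; j < mo.n; j++)
      for (int k = 0; k < D.K - 1; k++)
        E[s](j, k) = (st.logX[s](j, k + 1) - st.logX[s](j, k)) / D.delta[k]
                     - st.a1[j] + st.a2[j] * st.X[s](j, k);
  }

  // random visiting order via R RNG
  std::vector<int> order(mo.n);
  for (int i = 0; i < mo.n; i++) order[i] = i;
  for (int i = mo.n - 1; i > 0; i--) {
    int j = (int)std::floor(R::unif_rand() * (i + 1));
    std::swap(order[i], order[j]);
  }

  for (int oi = 0; oi < mo.n; oi++) {
    int i = order[oi];
    int old = st.c[i];
    arma::ivec counts(st.M, arma::fill::zeros);
    for (int j = 0; j < mo.n; j++) counts[st.c[j]]++;
    counts[old]--;

    int aux;
    bool aux_is_old = (counts[old] == 0);
    int M0 = st.M;
    if (aux_is_old) {
      aux = old;
    } else {
      // extend matrices; auxiliary-module indicators are drawn from their
      // conditional (Polya-urn) prior, coefficients are marginalized so
      // only placeholder values are needed
      aux = st.M;
      int Mn = st.M + 1;
      st.b.resize(Mn, Mn);  st.zb.resize(Mn, Mn);
      arma::mat gam2(mo.P, Mn, arma::fill::zeros);
      arma::imat zg2(mo.P, Mn, arma::fill::zeros);
      if (mo.P > 0) {
        gam2.cols(0, Mn - 2) = st.gam;
        zg2.cols(0, Mn - 2) = st.zg;
      }
      st.gam = gam2; st.zg = zg2;
      int kb = 0, nb = 0;
      for (int m = 0; m < M0; m++)
        for (int mp = 0; mp < M0; mp++)
          if (m != mp) { kb += st.zb(m, mp); nb++; }
      for (int m = 0; m < M0; m++) {
        double p1 = (mo.zb_a + kb) / (mo.zb_a + mo.zb_b + nb);
        st.zb(aux, m) = (R::unif_rand() < p1) ? 1 : 0;
        kb += st.zb(aux, m); nb++;
        p1 = (mo.zb_a + kb) / (mo.zb_a + mo.zb_b + nb);
        st.zb(m, aux) = (R::unif_rand() < p1) ? 1 : 0;
        kb += st.zb(m, aux); nb++;
        st.b(aux, m) = 0.0;
        st.b(m, aux) = 0.0;
      }
      st.b(aux, aux) = 0.0; st.zb(aux, aux) = 0;
      int kg = 0, ng = 0;
      if (mo.P > 0) {
        kg = arma::accu(st.zg); ng = mo.P * M0;
      }
      for (int p = 0; p < mo.P; p++) {
        double p1 = (mo.zg_a + kg) / (mo.zg_a + mo.zg_b + ng);
        st.zg(p, aux) = (R::unif_rand() < p1) ? 1 : 0;
        kg += st.zg(p, aux); ng++;
        st.gam(p, aux) = 0.0;
      }
    }
    int Mtot = aux_is_old ? st.M : st.M + 1;

    // module sums with x_i removed
    std::vector<arma::mat> Sbase(mo.S);
    for (int s = 0; s < mo.S; s++) {
      Sbase[s].zeros(Mtot, mo.subs[s].K);
      Sbase[s].rows(0, st.M - 1) = st.Smod[s];
      Sbase[s].row(old) -= st.X[s].row(i);
    }

    arma::vec lw(Mtot);
    for (int cand = 0; cand < Mtot; cand++) {
      double pw;
      if (cand == aux) pw = std::log(st.alpha);
      else if (counts[cand] > 0) pw = std::log((double)counts[cand]);
      else { lw[cand] = -arma::datum::inf; continue; }
      double ev = 0.0;
      for (int m = 0; m < Mtot; m++)
        ev += block_evidence(mo, st, m, cand, i, Mtot, Sbase, E);
      lw[cand] = pw + ev;
    }
    double mx = lw.max();
    arma::vec w = arma::exp(lw - mx);
    double tot = arma::accu(w);
    double u = R::unif_rand() * tot, csum = 0.0;
    int cnew = Mtot - 1;
    for (int m = 0; m < Mtot; m++) { csum += w[m]; if (u <= csum) { cnew = m; break; } }

    st.c[i] = cnew;
    if (!aux_is_old) {
      if (cnew == aux) {
        st.M = Mtot;                 // aux becomes a real module
      } else {
        // discard auxiliary module
        st.b = st.b.submat(0, 0, M0 - 1, M0 - 1);
        st.zb = st.zb.submat(0, 0, M0 - 1, M0 - 1);
        if (mo.P > 0) {
          st.gam = st.gam.cols(0, M0 - 1);
          st.zg = st.zg.cols(0, M0 - 1);
        } else {
          st.gam.set_size(0, M0); st.zg.set_size(0, M0);
        }
      }
    } else if (cnew != aux) {
      shed_module(st, aux);          // old module emptied for good
    }
    rebuild_caches(mo, st);
  }
  // coefficients were integrated out of the assignment moves; refresh them
  // from their full conditional under the new partition before any later
  // phase conditions on their values
  update_coefficients(mo, st);
}

// ---------------------------------------------------- variance + alpha
static void update_sw2(const Model& mo, State& st) {
  double shape = mo.w_shape, rate = mo.w_rate;
  for (int s = 0; s < mo.S; s++) {
    const Subj& D = mo.subs[s];
    for (int k = 0; k < D.K - 1; k++) {
      for (int i = 0; i < mo.n; i++) {
        double lmu = st.logX[s](i, k) + D.delta[k] * Fval(mo, st, s, i, k);
        double e = st.logX[s](i, k + 1) - lmu;
        shape += 0.5;
        rate += e * e / (2.0 * D.delta[k]);
      }
    }
  }
  st.sw2 = rate / R::rgamma(shape, 1.0);
  if (!std::isfinite(st.sw2) || st.sw2 < 1e-12) st.sw2 = 1e-12;
}

static void update_alpha(const Model& mo, State& st) {
  int N = mo.n, M = st.M;
  double eta = R::rbeta(st.alpha + 1.0, (double)N);
  double rate = mo.a_rate - std::log(eta);
  double odds = (mo.a_shape + M - 1.0) / (N * rate);
  double pi = odds / (1.0 + odds);
  double shape = (R::unif_rand() < pi) ? mo.a_shape + M : mo.a_shape + M - 1.0;
  st.alpha = R::rgamma(shape, 1.0) / rate;
  if (st.alpha < 1e-8) st.alpha = 1e-8;
}

// ------------------------------------------------------------- main entry
static Model parse_model(List data, List priors) {
  Model mo;
  List subs = data["subjects"];
  mo.S = subs.size();
  mo.d0 = as<double>(data["d0"]);
  mo.d1 = as<double>(data["d1"]);
  mo.relfloor = as<double>(data["relfloor"]);
  for (int s = 0; s < mo.S; s++) {
    List ss = subs[s];
    Subj d;
    d.Y = as<arma::mat>(ss["Y"]);
    d.r = as<arma::vec>(ss["r"]);
    d.qn = as<arma::vec>(ss["qn"]);
    d.qmean = as<arma::vec>(ss["qmean"]);
    d.qvar = as<arma::vec>(ss["qvar"]);
    d.delta = as<arma::vec>(ss["delta"]);
    d.H = as<arma::mat>(ss["H"]);
    d.K = d.Y.n_cols;
    mo.subs.push_back(d);
  }
  mo.n = mo.subs[0].Y.n_rows;
  mo.P = mo.subs[0].H.n_rows;
  mo.m_a1 = as<double>(priors["m_a1"]); mo.v_a1 = as<double>(priors["v_a1"]);
  mo.m_a2 = as<double>(priors["m_a2"]); mo.v_a2 = as<double>(priors["v_a2"]);
  mo.v_b = as<double>(priors["v_b"]);   mo.v_g = as<double>(priors["v_g"]);
  mo.w_shape = as<double>(priors["w_shape"]); mo.w_rate = as<double>(priors["w_rate"]);
  mo.a_shape = as<double>(priors["a_shape"]); mo.a_rate = as<double>(priors["a_rate"]);
  mo.zb_a = as<double>(priors["zb_a"]); mo.zb_b = as<double>(priors["zb_b"]);
  mo.zg_a = as<double>(priors["zg_a"]); mo.zg_b = as<double>(priors["zg_b"]);
  mo.x0_m = as<double>(priors["x0_m"]); mo.x0_v = as<double>(priors["x0_v"]);
  return mo;
}

static State parse_state(List state, const Model& mo) {
  State st;
  List lx = state["logX"];
  for (int s = 0; s < mo.S; s++) {
    st.logX.push_back(as<arma::mat>(lx[s]));
    st.X.push_back(arma::exp(st.logX[s]));
  }
  st.a1 = as<arma::vec>(state["a1"]);
  st.a2 = as<arma::vec>(state["a2"]);
  st.c = as<arma::ivec>(state["c"]) - 1;   // to 0-based
  st.b = as<arma::mat>(state["b"]);
  st.zb = as<arma::imat>(state["zb"]);
  st.gam = as<arma::mat>(state["gam"]);
  st.zg = as<arma::imat>(state["zg"]);
  st.sw2 = as<double>(state["sw2"]);
  st.alpha = as<double>(state["alpha"]);
  st.prop_sd = as<arma::vec>(state["prop_sd"]);
  st.M = st.c.max() + 1;
  rebuild_caches(mo, st);
  return st;
}

static List state_to_list(const State& st, const Model& mo) {
  List lx(mo.S);
  for (int s = 0; s < mo.S; s++) lx[s] = st.logX[s];
  return List::create(
    _["logX"] = lx, _["a1"] = st.a1, _["a2"] = st.a2,
    _["c"] = IntegerVector(wrap(st.c + 1)),
    _["b"] = st.b, _["zb"] = st.zb, _["gam"] = st.gam, _["zg"] = st.zg,
    _["sw2"] = st.sw2, _["alpha"] = st.alpha, _["prop_sd"] = st.prop_sd);
}

// [[Rcpp::export]]
List cpp_run_gibbs(List state, List data, List priors, List control) {
  Model mo = parse_model(data, priors);
  State st = parse_state(state, mo);

  int n_sweeps = as<int>(control["n_sweeps"]);
  bool do_latents = as<bool>(control["do_latents"]);
  bool do_coeffs = as<bool>(control["do_coeffs"]);
  bool do_ind_b = as<bool>(control["do_ind_b"]);
  bool do_ind_g = as<bool>(control["do_ind_g"]);
  bool do_modules = as<bool>(control["do_modules"]);
  bool do_sw2 = as<bool>(control["do_sw2"]);
  bool do_alpha = as<bool>(control["do_alpha"]);
  bool adapt = as<bool>(control["adapt"]);
  int record_start = as<int>(control["record_start"]); // 1-based, 0 = none
  int record_thin = as<int>(control["record_thin"]);
  int latent_every = as<int>(control["latent_every"]); // in recorded samples

  int n = mo.n, P = mo.P;
  int G = 0;
  if (record_start > 0)
    G = (n_sweeps - record_start) / record_thin + 1;

  arma::mat rec_a1(n, G), rec_a2(n, G);
  arma::imat rec_c(n, G);
  arma::vec rec_sw2(G), rec_alpha(G);
  arma::ivec rec_M(G);
  arma::mat rec_bt(n * n, G), rec_gt(P * n, G);
  arma::imat rec_zbt(n * n, G), rec_zgt(P * n, G);
  std::vector<List> rec_latents;

  arma::vec acc(n, arma::fill::zeros), tries(n, arma::fill::zeros);
  int g = 0;
  for (int sweep = 1; sweep <= n_sweeps; sweep++) {
    if (do_latents) update_latents(mo, st, acc, tries);
    if (do_coeffs) update_coefficients(mo, st);
    if (do_ind_b || do_ind_g) update_indicators(mo, st, do_ind_b, do_ind_g);
    if (do_modules) update_modules(mo, st);
    if (do_sw2) update_sw2(mo, st);
    if (do_alpha) update_alpha(mo, st);

    if (adapt && sweep % 50 == 0) {
      for (int i = 0; i < n; i++) {
        double a = (tries[i] > 0) ? acc[i] / tries[i] : 0.44;
        if (a < 0.25) st.prop_sd[i] *= 0.7;
        else if (a > 0.6) st.prop_sd[i] *= 1.4;
        st.prop_sd[i] = std::min(std::max(st.prop_sd[i], 1e-3), 5.0);
      }
      acc.zeros(); tries.zeros();
    }

    if (record_start > 0 && sweep >= record_start &&
        (sweep - record_start) % record_thin == 0 && g < G) {
      rec_a1.col(g) = st.a1; rec_a2.col(g) = st.a2;
      rec_c.col(g) = st.c + 1;
      rec_sw2[g] = st.sw2; rec_alpha[g] = st.alpha; rec_M[g] = st.M;
      for (int i = 0; i < n; i++) {
        for (int j = 0; j < n; j++) {
          int ci = st.c[i], cj = st.c[j];
          double val = 0.0; int zz = 0;
          if (i != j && ci != cj && st.zb(ci, cj)) {
            val = st.b(ci, cj); zz = 1;
          }
          // column-major so the R-side array has [i, j] = effect of j on i
          rec_bt(j * n + i, g) = val;
          rec_zbt(j * n + i, g) = zz;
        }
        for (int p = 0; p < P; p++) {
          int ci = st.c[i];
          rec_gt(p * n + i, g) = st.zg(p, ci) ? st.gam(p, ci) : 0.0;
          rec_zgt(p * n + i, g) = st.zg(p, ci);
        }
      }
      if (latent_every > 0 && g % latent_every == 0) {
        List lx(mo.S);
        for (int s = 0; s < mo.S; s++) lx[s] = st.logX[s];
        rec_latents.push_back(lx);
      }
      g++;
    }
  }

  List samples = R_NilValue;
  if (G > 0) {
    List lat(rec_latents.size());
    for (size_t u = 0; u < rec_latents.size(); u++) lat[u] = rec_latents[u];
    samples = List::create(
      _["a1"] = rec_a1, _["a2"] = rec_a2, _["c"] = rec_c,
      _["sw2"] = rec_sw2, _["alpha"] = rec_alpha, _["n_modules"] = rec_M,
      _["b_taxon"] = rec_bt, _["zb_taxon"] = rec_zbt,
      _["g_taxon"] = rec_gt, _["zg_taxon"] = rec_zgt,
      _["latents"] = lat);
  }
  arma::vec accfrac(n);
  for (int i = 0; i < n; i++) accfrac[i] = (tries[i] > 0) ? acc[i] / tries[i] : NA_REAL;
  return List::create(_["state"] = state_to_list(st, mo),
                      _["samples"] = samples,
                      _["acceptance"] = accfrac);
}
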