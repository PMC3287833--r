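// Reversible-jump MCMC core for oligogenic segregation analysis of a
// quantitative trait in pedigrees.
//
// Model: y = mu + X beta + sum_i [ a_i (g_i - 1) + d_i 1{g_i = 1} ] + e,
// e ~ N(0, sigma2_e), with the number of QTLs k a parameter of the model.
// Each QTL carries an allele frequency q, additive and dominance effects
// (a, d), and a descent-graph genotype representation: one binary allele
// per founder allele slot plus one segregation indicator per meiosis.
// Genotypes are derived by dropping founder alleles through the indicators,
// so every configuration is Mendelian-consistent by construction.
//
// Priors: k ~ Poisson(lambda) truncated to {0..kmax}; a, d ~ N(0, tau2);
// q ~ Uniform(qmin, qmax) (Beta(1,1) restricted); mu, beta flat;
// sigma2_e ~ Inverse-Gamma(ig_shape, ig_rate).
//
// Moves per iteration:
//  (a) joint conjugate update of (mu, beta, all a_i, d_i) given genotypes;
//  (b) conjugate update of sigma2_e;
//  (c) per QTL, Metropolis sweeps over founder alleles and segregation
//      indicators with selective propagation of allele changes to
//      descendants;
//  (d) conjugate update of each q from its founder alleles;
//  (e) one birth/death reversible-jump move with prior-draw proposals
//      (acceptance = likelihood ratio x p(k')/p(k); the proposal densities
//      of prior-drawn parameters cancel and the uniform-death /
//      append-birth bookkeeping cancels against the exchangeability
//      factor).

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Qtl {
  double q, a, d;
  std::vector<int> alleles;  // 2n slots, 0/1 rare-allele indicator
  std::vector<int> seg;      // 2n indicators (non-founders only)
  std::vector<int> g;        // genotype 0/1/2 per individual
};

inline double contrib(int g, double a, double d) {
  return a * (g - 1) + (g == 1 ? d : 0.0);
}

struct Sampler {
  int n, p;
  arma::vec y;
  arma::mat X;
  std::vector<int> fa, mo;            // -1 for founders; topo order
  std::vector<int> founder_idx;
  // children[i]: (child, side) pairs; side 0 = child's paternal slot
  std::vector<std::vector<std::pair<int, int>>> children;

  double lambda, tau2, ig_shape, ig_rate, qmin, qmax;
  int kmax;
  bool const_lik;

  std::vector<Qtl> qtls;
  arma::vec gamma_mu_beta;  // length 1+p (mu, beta)
  double sig2;
  arma::vec r;              // residual y - fit

  // scratch for selective propagation
  std::vector<int> stamp, gold_;
  std::vector<int> gch;                       // individuals with changed g
  std::vector<std::array<int, 3>> undo;       // (idx, slot, oldval)
  int epoch = 0;

  // acceptance counters
  long n_birth = 0, a_birth = 0, n_death = 0, a_death = 0;
  long n_fflip = 0, a_fflip = 0, n_sflip = 0, a_sflip = 0;

  void init(const arma::vec& y_, const arma::mat& X_,
            const IntegerVector& father, const IntegerVector& mother) {
    y = y_; X = X_; n = y.n_elem; p = X.n_cols;
    fa.assign(father.begin(), father.end());
    mo.assign(mother.begin(), mother.end());
    children.assign(n, {});
    for (int i = 0; i < n; ++i) {
      if (fa[i] < 0) founder_idx.push_back(i);
      else {
        children[fa[i]].push_back({i, 0});
        children[mo[i]].push_back({i, 1});
      }
    }
    stamp.assign(n, -1);
    gold_.assign(n, 0);
    gamma_mu_beta = arma::zeros(1 + p);
    gamma_mu_beta[0] = arma::mean(y);
    sig2 = arma::var(y);
    if (sig2 <= 0) sig2 = 1.0;
    r = y - fit_all();
  }

  arma::vec fit_all() const {
    arma::vec f(n, arma::fill::value(gamma_mu_beta[0]));
    for (int j = 0; j < p; ++j) f += X.col(j) * gamma_mu_beta[1 + j];
    for (const auto& Q : qtls)
      for (int i = 0; i < n; ++i) f[i] += contrib(Q.g[i], Q.a, Q.d);
    return f;
  }

  void drop_genotypes(Qtl& Q) const {
    for (int i = 0; i < n; ++i) {
      if (fa[i] >= 0) {
        Q.alleles[2 * i]     = Q.alleles[2 * fa[i] + Q.seg[2 * i]];
        Q.alleles[2 * i + 1] = Q.alleles[2 * mo[i] + Q.seg[2 * i + 1]];
      }
      Q.g[i] = Q.alleles[2 * i] + Q.alleles[2 * i + 1];
    }
  }

  Qtl prior_draw_qtl() const {
    Qtl Q;
    Q.q = R::runif(qmin, qmax);
    Q.a = R::norm_rand() * std::sqrt(tau2);
    Q.d = R::norm_rand() * std::sqrt(tau2);
    Q.alleles.assign(2 * n, 0);
    Q.seg.assign(2 * n, 0);
    Q.g.assign(n, 0);
    for (int f : founder_idx) {
      Q.alleles[2 * f]     = (unif_rand() < Q.q) ? 1 : 0;
      Q.alleles[2 * f + 1] = (unif_rand() < Q.q) ? 1 : 0;
    }
    for (int i = 0; i < n; ++i) {
      if (fa[i] >= 0) {
        Q.seg[2 * i]     = (unif_rand() < 0.5) ? 1 : 0;
        Q.seg[2 * i + 1] = (unif_rand() < 0.5) ? 1 : 0;
      }
    }
    drop_genotypes(Q);
    return Q;
  }

  // set allele slot (i, s) of Q to v, propagating to descendants whose
  // inherited copy traces to that slot; records undo + genotype changes
  void set_allele(Qtl& Q, int i, int s, int v) {
    int old = Q.alleles[2 * i + s];
    if (old == v) return;
    undo.push_back({i, s, old});
    Q.alleles[2 * i + s] = v;
    if (stamp[i] != epoch) { stamp[i] = epoch; gold_[i] = Q.g[i]; gch.push_back(i); }
    Q.g[i] += v - old;
    for (const auto& cs : children[i])
      if (Q.seg[2 * cs.first + cs.second] == s)
        set_allele(Q, cs.first, cs.second, v);
  }

  void begin_proposal() { ++epoch; undo.clear(); gch.clear(); }

  double delta_rss(const Qtl& Q) const {
    double d = 0.0;
    for (int i : gch) {
      double df = contrib(Q.g[i], Q.a, Q.d) - contrib(gold_[i], Q.a, Q.d);
      double rn = r[i] - df;
      d += rn * rn - r[i] * r[i];
    }
    return d;
  }

  void commit(const Qtl& Q) {
    for (int i : gch)
      r[i] -= contrib(Q.g[i], Q.a, Q.d) - contrib(gold_[i], Q.a, Q.d);
  }

  void rollback(Qtl& Q) {
    for (auto it = undo.rbegin(); it != undo.rend(); ++it)
      Q.alleles[2 * (*it)[0] + (*it)[1]] = (*it)[2];
    for (int i : gch) Q.g[i] = gold_[i];
  }

  bool accept_logratio(double logA) {
    return logA >= 0 || unif_rand() < std::exp(logA);
  }

  void genotype_sweep(Qtl& Q) {
    // founder allele flips
    double lq = std::log(Q.q / (1.0 - Q.q));
    for (int f : founder_idx) {
      for (int s = 0; s < 2; ++s) {
        ++n_fflip;
        int old = Q.alleles[2 * f + s];
        begin_proposal();
        set_allele(Q, f, s, 1 - old);
        double logA = (old == 0 ? lq : -lq);
        if (!const_lik) logA += -delta_rss(Q) / (2.0 * sig2);
        if (accept_logratio(logA)) { commit(Q); ++a_fflip; }
        else rollback(Q);
      }
    }
    // segregation indicator flips (symmetric prior)
    for (int i = 0; i < n; ++i) {
      if (fa[i] < 0) continue;
      for (int side = 0; side < 2; ++side) {
        ++n_sflip;
        int news = 1 - Q.seg[2 * i + side];
        int par = (side == 0) ? fa[i] : mo[i];
        int v = Q.alleles[2 * par + news];
        if (v == Q.alleles[2 * i + side]) {  // no genotype change
          Q.seg[2 * i + side] = news;
          ++a_sflip;
          continue;
        }
        begin_proposal();
        Q.seg[2 * i + side] = news;
        set_allele(Q, i, side, v);
        double logA = const_lik ? 0.0 : -delta_rss(Q) / (2.0 * sig2);
        if (accept_logratio(logA)) { commit(Q); ++a_sflip; }
        else { rollback(Q); Q.seg[2 * i + side] = 1 - news; }
      }
    }
  }

  void update_q(Qtl& Q) {
    int n1 = 0, ntot = 2 * (int)founder_idx.size();
    for (int f : founder_idx) n1 += Q.alleles[2 * f] + Q.alleles[2 * f + 1];
    double sh1 = 1.0 + n1, sh2 = 1.0 + (ntot - n1);
    double lo = R::pbeta(qmin, sh1, sh2, 1, 0);
    double hi = R::pbeta(qmax, sh1, sh2, 1, 0);
    double u = R::runif(lo, hi);
    double q = R::qbeta(u, sh1, sh2, 1, 0);
    Q.q = std::min(std::max(q, qmin), qmax);
  }

  void update_effects() {
    if (const_lik) return;
    int k = qtls.size();
    int m = 1 + p + 2 * k;
    arma::mat W(n, m);
    W.col(0).ones();
    for (int j = 0; j < p; ++j) W.col(1 + j) = X.col(j);
    for (int i = 0; i < k; ++i) {
      for (int t = 0; t < n; ++t) {
        W(t, 1 + p + 2 * i)     = qtls[i].g[t] - 1.0;
        W(t, 1 + p + 2 * i + 1) = (qtls[i].g[t] == 1) ? 1.0 : 0.0;
      }
    }
    arma::vec prec(m, arma::fill::value(1e-10));
    for (int j = 1 + p; j < m; ++j) prec[j] = 1.0 / tau2;
    arma::mat A = W.t() * W / sig2 + arma::diagmat(prec);
    arma::vec b = W.t() * y / sig2;
    arma::mat R_ = arma::chol(A);  // A = R'R
    arma::vec mean = arma::solve(A, b, arma::solve_opts::likely_sympd);
    arma::vec z(m);
    for (int j = 0; j < m; ++j) z[j] = R::norm_rand();
    arma::vec gam = mean + arma::solve(arma::trimatu(R_), z);
    gamma_mu_beta = gam.head(1 + p);
    for (int i = 0; i < k; ++i) {
      qtls[i].a = gam[1 + p + 2 * i];
      qtls[i].d = gam[1 + p + 2 * i + 1];
    }
    r = y - W * gam;
  }

  void update_sigma() {
    if (const_lik) return;
    double rss = arma::dot(r, r);
    double shape = ig_shape + 0.5 * n;
    double rate = ig_rate + 0.5 * rss;
    sig2 = rate / R::rgamma(shape, 1.0);
  }

  void birth_death() {
    int k = qtls.size();
    if (unif_rand() < 0.5) {  // birth
      ++n_birth;
      if (k >= kmax) return;  // auto-reject at the cap
      Qtl Q = prior_draw_qtl();
      double logA = std::log(lambda / (k + 1.0));
      if (!const_lik) {
        double d = 0.0;
        for (int i = 0; i < n; ++i) {
          double rn = r[i] - contrib(Q.g[i], Q.a, Q.d);
          d += rn * rn - r[i] * r[i];
        }
        logA += -d / (2.0 * sig2);
      }
      if (accept_logratio(logA)) {
        if (!const_lik)
          for (int i = 0; i < n; ++i) r[i] -= contrib(Q.g[i], Q.a, Q.d);
        qtls.push_back(std::move(Q));
        ++a_birth;
      }
    } else {  // death
      ++n_death;
      if (k == 0) return;
      int j = std::min((int)(unif_rand() * k), k - 1);
      const Qtl& Q = qtls[j];
      double logA = std::log(k / lambda);
      if (!const_lik) {
        double d = 0.0;
        for (int i = 0; i < n; ++i) {
          double rn = r[i] + contrib(Q.g[i], Q.a, Q.d);
          d += rn * rn - r[i] * r[i];
        }
        logA += -d / (2.0 * sig2);
      }
      if (accept_logratio(logA)) {
        if (!const_lik)
          for (int i = 0; i < n; ++i) r[i] += contrib(Q.g[i], Q.a, Q.d);
        qtls.erase(qtls.begin() + j);
        ++a_death;
      }
    }
  }

  void iterate() {
    update_effects();
    update_sigma();
    for (auto& Q : qtls) genotype_sweep(Q);
    for (auto& Q : qtls) update_q(Q);
    birth_death();
  }
};

}  // namespace

// [[Rcpp::export(name = ".seg_mcmc_cpp")]]
List seg_mcmc_cpp(const arma::vec& y, const arma::mat& X,
                  const IntegerVector& father, const IntegerVector& mother,
                  double lambda, int kmax, double tau2,
                  double ig_shape, double ig_rate,
                  double qmin, double qmax,
                  int burnin, int n_samples, int thin, bool constant_lik) {
  if (n_samples <= 0) stop("number of retained samples must be positive");
  if (thin < 1) stop("thin must be >= 1");
  Sampler S;
  S.lambda = lambda; S.kmax = kmax; S.tau2 = tau2;
  S.ig_shape = ig_shape; S.ig_rate = ig_rate;
  S.qmin = qmin; S.qmax = qmax; S.const_lik = constant_lik;
  S.init(y, X, father, mother);

  int p = S.p, n = S.n;
  arma::vec varX(p), tmp(n);
  double varY = arma::var(y);
  for (int j = 0; j < p; ++j) varX[j] = arma::var(S.X.col(j));

  IntegerVector k_out(n_samples);
  NumericMatrix shares(n_samples, p + 2);

  for (int it = 0; it < burnin; ++it) S.iterate();
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thin; ++t) S.iterate();
    k_out[s] = S.qtls.size();
    if (!constant_lik && varY > 0) {
      for (int j = 0; j < p; ++j)
        shares(s, j) = S.gamma_mu_beta[1 + j] * S.gamma_mu_beta[1 + j] *
                       varX[j] / varY;
      tmp.zeros();
      for (const auto& Q : S.qtls)
        for (int i = 0; i < n; ++i) tmp[i] += contrib(Q.g[i], Q.a, Q.d);
      shares(s, p) = S.qtls.empty() ? 0.0 : arma::var(tmp) / varY;
      shares(s, p + 1) = S.sig2 / varY;
    }
  }

  return List::create(
    _["k"] = k_out,
    _["shares"] = shares,
    _["accept"] = NumericVector::create(
      _["birth"] = S.n_birth ? (double)S.a_birth / S.n_birth : NA_REAL,
      _["death"] = S.n_death ? (double)S.a_death / S.n_death : NA_REAL,
      _["founder_allele"] = S.n_fflip ? (double)S.a_fflip / S.n_fflip : NA_REAL,
      _["segregation"] = S.n_sflip ? (double)S.a_sflip / S.n_sflip : NA_REAL));
}
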