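// Phylogenetic likelihood engine: Felsenstein pruning over an arbitrary
// rooted tree (multifurcations allowed), rate-category mixtures, and
// coordinate-cycling ML fits for the Goldman-Yang branch codon model and
// GTR+Gamma+I. Eigen-decomposition of the (reversible) rate matrices is
// done once per parameter update via symmetrization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SCALE_THRESH = 1e-240;

// ---------------------------------------------------------------------------
// Brent 1-D maximization (classic localmin on -f), bounded.
// ---------------------------------------------------------------------------
template <typename F>
static double brent_max(F f, double lo, double hi, double tol, double &fbest,
                        int maxit = 60) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  fbest = fx;
  return x;
}

// ---------------------------------------------------------------------------
// Eigen system of a reversible rate matrix (via pi-symmetrization)
// ---------------------------------------------------------------------------
struct EigQ {
  mat U;    // right eigenvectors (columns)
  mat Vi;   // inverse = left eigenvectors (rows)
  vec lam;  // eigenvalues
};

static EigQ eig_reversible(const mat &Q, const vec &pi) {
  int n = Q.n_rows;
  vec sp = sqrt(pi);
  mat B(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) B(i, j) = sp(i) * Q(i, j) / sp(j);
  B = 0.5 * (B + B.t());  // symmetrize numerically
  vec ev; mat W;
  eig_sym(ev, W, B);
  EigQ e;
  e.lam = ev;
  e.U = W;  e.U.each_col() /= sp;
  e.Vi = W.t(); e.Vi.each_row() %= sp.t();
  return e;
}

static mat pmat(const EigQ &e, double t) {
  vec el = exp(e.lam * t);
  mat P = e.U * diagmat(el) * e.Vi;
  P.clamp(0.0, datum::inf);
  return P;
}

// ---------------------------------------------------------------------------
// Engine context
// ---------------------------------------------------------------------------
struct Engine {
  int nstate, ntip, nnode, nedge, ncat, npat, nclass;
  umat edge;        // nedge x 2, 0-based (parent, child), postorder
  vec elen;
  uvec eclass;      // 0-based class per edge
  std::vector<EigQ> eig;   // per class
  vec rates, rw;    // mixture category rates / weights (length ncat)
  vec pi, patw;
  cube tipc;        // nstate x npat x ntip
  int root;
  std::vector<std::vector<int>> chedge;  // per node: incident child edge ids
  std::vector<int> paredge;              // per node: edge above (-1 root)

  // caches
  std::vector<cube> M;     // per edge: P_e * down[child]  (nstate x npat x ncat)
  std::vector<cube> down;  // per internal node
  std::vector<cube> up;    // per node (child side of its parent edge)
  vec clog;                // per-pattern log scale accumulator

  void init_topology() {
    root = (int)edge(nedge - 1, 0);
    chedge.assign(nnode, {});
    paredge.assign(nnode, -1);
    for (int e = 0; e < nedge; ++e) {
      chedge[edge(e, 0)].push_back(e);
      paredge[edge(e, 1)] = e;
    }
    M.assign(nedge, cube());
    down.assign(nnode, cube());
    up.assign(nnode, cube());
  }

  const cube &down_of(int v) {
    // tips: build a cube view lazily (replicate tip partial across cats)
    if (v < ntip) {
      if (down[v].n_elem == 0) {
        down[v].set_size(nstate, npat, ncat);
        for (int c = 0; c < ncat; ++c) down[v].slice(c) = tipc.slice(v);
      }
      return down[v];
    }
    return down[v];
  }

  void edge_P_into_M(int e) {
    const cube &dv = down_of((int)edge(e, 1));
    if (M[e].n_elem == 0) M[e].set_size(nstate, npat, ncat);
    for (int c = 0; c < ncat; ++c) {
      mat P = pmat(eig[eclass(e)], elen(e) * rates(c));
      M[e].slice(c) = P * dv.slice(c);
    }
  }

  // recompute down[p] for internal p from current child M's; rescale
  void refresh_down(int p) {
    cube &dp = down[p];
    if (dp.n_elem == 0) dp.set_size(nstate, npat, ncat);
    dp.ones();
    for (int e : chedge[p])
      for (int c = 0; c < ncat; ++c) dp.slice(c) %= M[e].slice(c);
  }

  void full_down() {
    clog.zeros(npat);
    for (int e = 0; e < nedge; ++e) {
      int v = (int)edge(e, 1);
      if (v >= ntip) {
        refresh_down(v);
        rescale(v);
      }
      edge_P_into_M(e);
    }
    refresh_down(root);
    rescale(root);
  }

  void rescale(int v) {
    // per-pattern scaling of down[v] to avoid underflow
    cube &dv = down[v];
    for (int s = 0; s < npat; ++s) {
      double mx = 0.0;
      for (int c = 0; c < ncat; ++c) {
        double m = dv.slice(c).col(s).max();
        if (m > mx) mx = m;
      }
      if (mx < SCALE_THRESH && mx > 0.0) {
        for (int c = 0; c < ncat; ++c) dv.slice(c).col(s) /= mx;
        clog(s) += std::log(mx);
      }
    }
  }

  double root_loglik() {
    double ll = 0.0;
    const cube &dr = down[root];
    for (int s = 0; s < npat; ++s) {
      double lik = 0.0;
      for (int c = 0; c < ncat; ++c)
        lik += rw(c) * dot(pi, dr.slice(c).col(s));
      ll += patw(s) * (std::log(lik) + clog(s));
    }
    return ll;
  }

  double full_loglik() {
    full_down();
    return root_loglik();
  }

  // up partials: up[v] such that sitelik = sum_i up[v](i) * (P_e down[v])(i)
  void full_up() {
    // process edges in reverse postorder (parents before children)
    for (int e = nedge - 1; e >= 0; --e) {
      int p = (int)edge(e, 0), v = (int)edge(e, 1);
      cube &uv = up[v];
      if (uv.n_elem == 0) uv.set_size(nstate, npat, ncat);
      if (p == root) {
        for (int c = 0; c < ncat; ++c) {
          mat base(nstate, npat);
          base.each_col() = pi;
          for (int f : chedge[p]) if (f != e) base %= M[f].slice(c);
          uv.slice(c) = base;
        }
      } else {
        int fe = paredge[p];
        for (int c = 0; c < ncat; ++c) {
          mat P = pmat(eig[eclass(fe)], elen(fe) * rates(c));
          mat base = P.t() * up[p].slice(c);
          for (int f : chedge[p]) if (f != e) base %= M[f].slice(c);
          uv.slice(c) = base;
        }
      }
    }
  }

  // one sweep of per-branch Brent optimizations; returns exact lnL after.
  // Per edge, the profile likelihood in its length is diagonalized once:
  //   A_cat = (U' up[v]) .% (Vi down[v]),  sitelik_cat(t) = exp(lam t r_c)' A_cat
  // so each Brent trial costs one nstate x npat weighting.
  double sweep_branches(const uvec &free_edge, double tmin, double tmax) {
    full_down();
    cube A(nstate, npat, ncat);
    // preorder (reverse postorder): refresh up[v] from the already-updated
    // parent caches so every edge is optimized against current lengths
    for (int e = nedge - 1; e >= 0; --e) {
      int p = (int)edge(e, 0);
      int v = (int)edge(e, 1);
      cube &uv_ref = up[v];
      if (uv_ref.n_elem == 0) uv_ref.set_size(nstate, npat, ncat);
      if (p == root) {
        for (int c = 0; c < ncat; ++c) {
          mat base(nstate, npat);
          base.each_col() = pi;
          for (int f : chedge[p]) if (f != e) base %= M[f].slice(c);
          uv_ref.slice(c) = base;
        }
      } else {
        int fe = paredge[p];
        for (int c = 0; c < ncat; ++c) {
          mat P = pmat(eig[eclass(fe)], elen(fe) * rates(c));
          mat base = P.t() * up[p].slice(c);
          for (int f : chedge[p]) if (f != e) base %= M[f].slice(c);
          uv_ref.slice(c) = base;
        }
      }
      if (!free_edge(e)) continue;
      const cube &dv = down_of(v);
      const cube &uv = up[v];
      const EigQ &eg = eig[eclass(e)];
      for (int c = 0; c < ncat; ++c)
        A.slice(c) = (eg.U.t() * uv.slice(c)) % (eg.Vi * dv.slice(c));
      auto f = [&](double t) {
        vec lik(npat, fill::zeros);
        for (int c = 0; c < ncat; ++c) {
          rowvec el = exp(eg.lam.t() * (t * rates(c)));
          lik += rw(c) * (el * A.slice(c)).t();
        }
        double ll = 0.0;
        for (int s = 0; s < npat; ++s) {
          double l = std::max(lik(s), 1e-300);
          ll += patw(s) * (std::log(l) + clog(s));
        }
        return ll;
      };
      double t0 = elen(e);
      double lo = std::max(tmin, 0.2 * t0 - 0.005);
      double hi = std::min(tmax, 4.0 * t0 + 0.05);
      double f0 = f(t0);
      double fb;
      double tbest = brent_max(f, lo, hi, 8e-4, fb, 40);
      if (fb > f0) elen(e) = tbest;
      edge_P_into_M(e);
    }
    return full_loglik();
  }
};

static Engine make_engine(const arma::umat &edge, const arma::vec &elen,
                          const arma::uvec &eclass, const arma::vec &rates,
                          const arma::vec &rw, const arma::vec &pi,
                          const arma::cube &tipc, const arma::vec &patw) {
  Engine en;
  en.edge = edge; en.elen = elen; en.eclass = eclass;
  en.rates = rates; en.rw = rw; en.pi = pi; en.tipc = tipc; en.patw = patw;
  en.nstate = tipc.n_rows; en.npat = tipc.n_cols; en.ntip = tipc.n_slices;
  en.nedge = edge.n_rows; en.ncat = rates.n_elem;
  en.nclass = eclass.max() + 1;
  int mx = en.ntip;
  for (int e = 0; e < en.nedge; ++e) {
    mx = std::max(mx, (int)edge(e, 0) + 1);
    mx = std::max(mx, (int)edge(e, 1) + 1);
  }
  en.nnode = mx;
  en.init_topology();
  return en;
}

// ---------------------------------------------------------------------------
// Rate matrix builders
// ---------------------------------------------------------------------------

// ctype: 0 = not single-nt change, 1 = syn transversion, 2 = syn transition,
//        3 = nonsyn transversion, 4 = nonsyn transition
static mat codon_Q(const imat &ctype, const vec &pi, double kappa,
                   double omega, bool scale) {
  int n = pi.n_elem;
  mat Q(n, n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      int t = ctype(i, j);
      if (i == j || t == 0) continue;
      double r = pi(j);
      if (t == 2 || t == 4) r *= kappa;
      if (t >= 3) r *= omega;
      Q(i, j) = r;
    }
    Q(i, i) = -accu(Q.row(i));
  }
  if (scale) {
    double mu = -dot(pi, Q.diag());
    if (mu > 0) Q /= mu;
  }
  return Q;
}

static mat gtr_Q(const vec &exch, const vec &pi, bool scale) {
  // exch order: AC, AG, AT, CG, CT, GT ; states A,C,G,T
  mat Q(4, 4, fill::zeros);
  int idx[4][4] = {{-1, 0, 1, 2}, {0, -1, 3, 4}, {1, 3, -1, 5}, {2, 4, 5, -1}};
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      if (i == j) continue;
      Q(i, j) = exch(idx[i][j]) * pi(j);
    }
    Q(i, i) = -accu(Q.row(i));
  }
  if (scale) {
    double mu = -dot(pi, Q.diag());
    if (mu > 0) Q /= mu;
  }
  return Q;
}

// mean rates of k equal-probability segments of Gamma(alpha, alpha)
static vec gamma_cat_rates(double alpha, int k) {
  vec r(k);
  if (k == 1) { r(0) = 1.0; return r; }
  for (int i = 0; i < k; ++i) {
    double lo = (double)i / k, hi = (double)(i + 1) / k;
    double qlo = (i == 0) ? 0.0 : R::qgamma(lo, alpha, 1.0 / alpha, 1, 0);
    double qhi = (i == k - 1) ? datum::inf
                              : R::qgamma(hi, alpha, 1.0 / alpha, 1, 0);
    // segment mean via incomplete gamma of shape alpha+1
    double plo = (i == 0) ? 0.0 : R::pgamma(qlo, alpha + 1.0, 1.0 / alpha, 1, 0);
    double phi = (i == k - 1) ? 1.0 : R::pgamma(qhi, alpha + 1.0, 1.0 / alpha, 1, 0);
    r(i) = (phi - plo) * k;
  }
  r *= 1.0 / mean(r) * 1.0;  // guard: exact unit mean
  return r;
}

// [[Rcpp::export(name = ".cpp_gamma_rates")]]
arma::vec cpp_gamma_rates(double alpha, int k) { return gamma_cat_rates(alpha, k); }

// Build mixture categories for Gamma+I given alpha, pinv
static void gi_cats(double alpha, double pinv, int k, vec &rates, vec &rw) {
  rates.set_size(k + 1);
  rw.set_size(k + 1);
  rates(0) = 0.0; rw(0) = pinv;
  vec g = gamma_cat_rates(alpha, k);
  double s = (pinv < 1.0) ? 1.0 / (1.0 - pinv) : 1.0;
  for (int i = 0; i < k; ++i) { rates(i + 1) = g(i) * s; rw(i + 1) = (1.0 - pinv) / k; }
}

// ---------------------------------------------------------------------------
// Exported: generic mixture log-likelihood given eigen systems from R
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_loglik_eig")]]
double cpp_loglik_eig(const arma::umat &edge, const arma::vec &elen,
                      const arma::uvec &eclass, const Rcpp::List &eigs,
                      const arma::vec &rates, const arma::vec &rw,
                      const arma::vec &pi, const arma::cube &tipc,
                      const arma::vec &patw) {
  Engine en = make_engine(edge, elen, eclass, rates, rw, pi, tipc, patw);
  en.eig.resize(eigs.size());
  for (int c = 0; c < (int)eigs.size(); ++c) {
    Rcpp::List e = eigs[c];
    en.eig[c].U = Rcpp::as<mat>(e["U"]);
    en.eig[c].lam = Rcpp::as<vec>(e["lam"]);
    en.eig[c].Vi = Rcpp::as<mat>(e["Vi"]);
  }
  return en.full_loglik();
}

// ---------------------------------------------------------------------------
// Exported: codon branch-model fit
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fit_codon")]]
Rcpp::List cpp_fit_codon(const arma::umat &edge, const arma::vec &elen0,
                          const arma::uvec &eclass, const arma::imat &ctype,
                          const arma::vec &pi, const arma::cube &tipc,
                          const arma::vec &patw, double kappa0,
                          const arma::vec &omega0, const arma::uvec &free_edge,
                          bool free_kappa, const arma::uvec &free_omega,
                          int maxcyc, double tol, double tmax, double kmin,
                          double kmax, double omin, double omax) {
  vec rates(1, fill::ones), rw(1, fill::ones);
  Engine en = make_engine(edge, elen0, eclass, rates, rw, pi, tipc, patw);
  int nclass = en.nclass;
  double kappa = kappa0;
  vec omega = omega0;

  auto rebuild = [&](int cls) {
    if ((int)en.eig.size() != nclass) en.eig.resize(nclass);
    for (int c = 0; c < nclass; ++c) {
      if (cls >= 0 && c != cls) continue;
      en.eig[c] = eig_reversible(codon_Q(ctype, pi, kappa, omega(c), true), pi);
    }
  };
  rebuild(-1);
  double lnl = en.full_loglik();
  double lnl0 = lnl;

  bool any_free_edge = any(free_edge);
  bool any_free = any_free_edge || free_kappa || any(free_omega);
  int cyc = 0;
  bool converged = !any_free;
  double bw_k = std::log(kmax) - std::log(kmin);
  double bw_o = std::log(omax) - std::log(omin);
  // adaptive bracket widths: shrink toward 4x the last move of each param
  double wk = bw_k;
  vec wo(nclass); wo.fill(bw_o);
  for (; cyc < maxcyc && any_free; ++cyc) {
    double prev = lnl;
    if (any_free_edge) lnl = en.sweep_branches(free_edge, 1e-9, tmax);
    if (free_kappa) {
      double lk = std::log(kappa);
      double lo = std::max(std::log(kmin), lk - wk);
      double hi = std::min(std::log(kmax), lk + wk);
      double fb;
      double best = brent_max(
          [&](double x) {
            kappa = std::exp(x);
            rebuild(-1);
            return en.full_loglik();
          },
          lo, hi, 2e-3, fb, 30);
      wk = std::min(1.0, std::max(0.12, 4.0 * std::fabs(best - lk)));
      if (best <= lo + 1e-8 || best >= hi - 1e-8) wk = std::min(bw_k, 4.0 * wk);
      kappa = std::exp(best);
      rebuild(-1);
      lnl = en.full_loglik();
    }
    for (int c = 0; c < nclass; ++c) {
      if (!free_omega(c)) continue;
      double lo0 = std::log(omega(c));
      double lo = std::max(std::log(omin), lo0 - wo(c));
      double hi = std::min(std::log(omax), lo0 + wo(c));
      double fb;
      double best = brent_max(
          [&](double x) {
            omega(c) = std::exp(x);
            rebuild(c);
            return en.full_loglik();
          },
          lo, hi, 2e-3, fb, 30);
      wo(c) = std::min(1.2, std::max(0.12, 4.0 * std::fabs(best - lo0)));
      if (best <= lo + 1e-8 || best >= hi - 1e-8) {
        wo(c) = std::min(bw_o, 4.0 * wo(c));
      }
      omega(c) = std::exp(best);
      rebuild(c);
      lnl = en.full_loglik();
    }
    if (lnl - prev < tol && cyc > 0) { converged = true; ++cyc; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("loglik") = lnl, Rcpp::Named("elen") = en.elen,
      Rcpp::Named("kappa") = kappa, Rcpp::Named("omega") = omega,
      Rcpp::Named("cycles") = cyc, Rcpp::Named("converged") = converged,
      Rcpp::Named("loglik0") = lnl0);
}

// ---------------------------------------------------------------------------
// Exported: nucleotide GTR+Gamma+I fit
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fit_nuc")]]
Rcpp::List cpp_fit_nuc(const arma::umat &edge, const arma::vec &elen0,
                       const arma::vec &exch, const arma::vec &pi,
                       const arma::cube &tipc, const arma::vec &patw,
                       double alpha0, double pinv0, int kcat,
                       const arma::uvec &free_edge, bool free_alpha,
                       bool free_pinv, int maxcyc, double tol, double tmax) {
  double alpha = alpha0, pinv = pinv0;
  vec rates, rw;
  gi_cats(alpha, pinv, kcat, rates, rw);
  uvec eclass(edge.n_rows, fill::zeros);
  Engine en = make_engine(edge, elen0, eclass, rates, rw, pi, tipc, patw);
  en.eig.resize(1);
  en.eig[0] = eig_reversible(gtr_Q(exch, pi, true), pi);

  auto set_cats = [&]() {
    gi_cats(alpha, pinv, kcat, en.rates, en.rw);
  };
  double lnl = en.full_loglik();
  double lnl0 = lnl;
  bool any_free_edge = any(free_edge);
  bool any_free = any_free_edge || free_alpha || free_pinv;
  int cyc = 0;
  bool converged = !any_free;
  for (; cyc < maxcyc && any_free; ++cyc) {
    double prev = lnl;
    if (any_free_edge) lnl = en.sweep_branches(free_edge, 1e-9, tmax);
    if (free_alpha) {
      double w = (cyc == 0) ? 4.0 : 1.0;
      double la = std::log(alpha);
      double fb;
      double best = brent_max(
          [&](double x) {
            alpha = std::exp(x);
            set_cats();
            return en.full_loglik();
          },
          std::max(std::log(0.05), la - w), std::min(std::log(100.0), la + w),
          1e-3, fb, 30);
      alpha = std::exp(best);
      set_cats();
      lnl = en.full_loglik();
    }
    if (free_pinv) {
      double fb;
      double best = brent_max(
          [&](double x) {
            pinv = x;
            set_cats();
            return en.full_loglik();
          },
          1e-6, 0.75, 1e-3, fb, 30);
      pinv = best;
      set_cats();
      lnl = en.full_loglik();
    }
    if (lnl - prev < tol && cyc > 0) { converged = true; ++cyc; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("loglik") = lnl, Rcpp::Named("elen") = en.elen,
      Rcpp::Named("alpha") = alpha, Rcpp::Named("p_inv") = pinv,
      Rcpp::Named("cycles") = cyc, Rcpp::Named("converged") = converged,
      Rcpp::Named("loglik0") = lnl0);
}

// ---------------------------------------------------------------------------
// Exported: plain codon / nucleotide log-likelihood (no fitting)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_loglik_codon")]]
double cpp_loglik_codon(const arma::umat &edge, const arma::vec &elen,
                        const arma::uvec &eclass, const arma::imat &ctype,
                        const arma::vec &pi, const arma::cube &tipc,
                        const arma::vec &patw, double kappa,
                        const arma::vec &omega) {
  vec rates(1, fill::ones), rw(1, fill::ones);
  Engine en = make_engine(edge, elen, eclass, rates, rw, pi, tipc, patw);
  en.eig.resize(en.nclass);
  for (int c = 0; c < en.nclass; ++c)
    en.eig[c] = eig_reversible(codon_Q(ctype, pi, kappa, omega(c), true), pi);
  return en.full_loglik();
}

// [[Rcpp::export(name = ".cpp_loglik_nuc")]]
double cpp_loglik_nuc(const arma::umat &edge, const arma::vec &elen,
                      const arma::vec &exch, const arma::vec &pi,
                      const arma::cube &tipc, const arma::vec &patw,
                      double alpha, double pinv, int kcat) {
  vec rates, rw;
  gi_cats(alpha, pinv, kcat, rates, rw);
  uvec eclass(edge.n_rows, fill::zeros);
  Engine en = make_engine(edge, elen, eclass, rates, rw, pi, tipc, patw);
  en.eig.resize(1);
  en.eig[0] = eig_reversible(gtr_Q(exch, pi, true), pi);
  return en.full_loglik();
}

// ---------------------------------------------------------------------------
// Exported: Fitch parsimony score (for topology pre-screening)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fitch")]]
double cpp_fitch(const arma::umat &edge, const arma::umat &tipbits,
                 const arma::vec &patw) {
  // tipbits: ntip x npat bitmasks (4-bit for nucleotides); 0 -> all states
  int nedge = edge.n_rows, npat = tipbits.n_cols, ntip = tipbits.n_rows;
  int nnode = edge.max() + 1;
  umat state(nnode, npat, fill::zeros);
  for (int i = 0; i < ntip; ++i) state.row(i) = tipbits.row(i);
  for (int i = ntip; i < nnode; ++i) state.row(i).fill(0u);
  vec score(npat, fill::zeros);
  std::vector<bool> seen(nnode, false);
  for (int e = 0; e < nedge; ++e) {
    int p = (int)edge(e, 0), v = (int)edge(e, 1);
    for (int s = 0; s < npat; ++s) {
      unsigned sv = state(v, s);
      if (sv == 0u) sv = 15u;
      if (!seen[p]) { state(p, s) = sv; continue; }
      unsigned in = state(p, s) & sv;
      if (in) state(p, s) = in;
      else { state(p, s) = state(p, s) | sv; score(s) += 1.0; }
    }
    seen[p] = true;
  }
  return dot(score, patw);
}
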