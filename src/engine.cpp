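// Felsenstein-pruning likelihood engine with discrete-gamma + invariant-site
// mixing, per-pattern log scaling, and coordinate-wise branch-length
// optimization (Brent line search edge by edge).
//
// The optimizer sweeps edges in preorder (root -> tips). Within a sweep the
// cached conditional likelihoods stay exact: "down" partials depend only on
// edge lengths below a node (not yet changed while descending) and "out"
// partials are recomputed immediately after the edge above them is
// re-optimized. Each edge's likelihood profile is projected onto the
// eigenbasis once, so a line-search evaluation costs one small
// matrix-vector product per rate category.
//
// Conventions: nodes are 0-based (tips 0..ntip-1); edges arrive in ape
// postorder so every child's subtree is complete before its parent edge.
// Tip states are 0-based, -1 = gap/missing. Transition probabilities come
// from the symmetric eigendecomposition P(t) = V diag(exp(lambda t)) W.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

namespace {

struct Engine {
  int E, nnode, ntip, ns, npat, nc, root;
  arma::imat edge;            // E x 2, 0-based (parent, child)
  vec lens;
  rowvec w;                   // pattern weights
  mat V, W;
  vec lam, pi, rates, rw;     // rw sums to 1 - pinv
  double pinv;
  arma::ivec cs;              // per pattern: 1..ns constant-capable state,
                              // -1 all-missing, 0 neither
  std::vector<uvec> tipidx;   // per tip: pattern state index, ns = missing
  mat Wg;                     // [W, W*1] for gathering tip-side projections
  vec log_pinv_term;          // per pattern: log(pinv * pi[cs]) or -inf
  std::vector<std::vector<int>> child_edges;  // per node
  std::vector<mat> down, msg, out;            // indexed node*nc+k / e*nc+k
  std::vector<rowvec> lsd, lso;               // log scale factors

  void init(const IntegerMatrix& edge_, const NumericVector& lens_,
            int nnode_, int ntip_, const IntegerMatrix& tip_,
            const NumericVector& w_, const NumericMatrix& V_,
            const NumericMatrix& W_, const NumericVector& lam_,
            const NumericVector& pi_, const NumericVector& rates_,
            const NumericVector& rw_, double pinv_,
            const IntegerVector& cs_) {
    E = edge_.nrow(); nnode = nnode_; ntip = ntip_;
    ns = V_.nrow(); npat = tip_.ncol(); nc = rates_.size();
    edge.set_size(E, 2);
    for (int e = 0; e < E; ++e) {
      edge(e, 0) = edge_(e, 0) - 1;
      edge(e, 1) = edge_(e, 1) - 1;
    }
    lens = as<vec>(lens_);
    tipidx.assign(ntip, uvec());
    for (int i = 0; i < ntip; ++i) {
      uvec ix(npat);
      for (int j = 0; j < npat; ++j)
        ix(j) = tip_(i, j) > 0 ? (arma::uword)(tip_(i, j) - 1)
                               : (arma::uword)ns;  // column ns = missing
      tipidx[i] = ix;
    }
    w = as<rowvec>(w_);
    V = as<mat>(V_); W = as<mat>(W_);
    lam = as<vec>(lam_); pi = as<vec>(pi_);
    Wg.set_size(ns, ns + 1);
    Wg.head_cols(ns) = W;
    Wg.col(ns) = arma::sum(W, 1);
    rates = as<vec>(rates_); rw = as<vec>(rw_);
    pinv = pinv_;
    cs = as<arma::ivec>(cs_);
    log_pinv_term.set_size(npat);
    for (int j = 0; j < npat; ++j) {
      if (pinv > 0.0 && cs(j) != 0) {
        double pc = cs(j) == -1 ? 1.0 : pi(cs(j) - 1);
        log_pinv_term(j) = std::log(pinv * pc);
      } else {
        log_pinv_term(j) = -arma::datum::inf;
      }
    }
    child_edges.assign(nnode, {});
    std::vector<bool> ischild(nnode, false);
    for (int e = 0; e < E; ++e) {
      child_edges[edge(e, 0)].push_back(e);
      ischild[edge(e, 1)] = true;
    }
    root = -1;
    for (int v = 0; v < nnode; ++v)
      if (!child_edges[v].empty() && !ischild[v]) root = v;
    down.assign((size_t)nnode * nc, mat());
    msg.assign((size_t)E * nc, mat());
    out.assign((size_t)nnode * nc, mat());
    lsd.assign(nnode, rowvec());
    lso.assign(nnode, rowvec());
  }

  // P(t) with a trailing all-ones column so missing tip states gather 1
  mat pmat_g(double t) const {
    vec e = arma::exp(lam * t);
    mat Wt = W;
    Wt.each_col() %= e;
    mat P(ns, ns + 1);
    P.head_cols(ns) = V * Wt;
    P.head_cols(ns).transform([](double x) { return x < 0.0 ? 0.0 : x; });
    P.col(ns).ones();
    return P;
  }

  // conditional likelihood message arriving at the parent along edge e
  mat edge_msg(const mat& Pg, int e, int k) const {
    int c = edge(e, 1);
    if (c < ntip) return Pg.cols(tipidx[c]);
    return Pg.head_cols(ns) * down[(size_t)c * nc + k];
  }

  void down_pass() {
    std::vector<int> seen(nnode, 0);
    for (int v = 0; v < ntip; ++v) lsd[v] = rowvec(npat, arma::fill::zeros);
    for (int e = 0; e < E; ++e) {
      int p = edge(e, 0);
      for (int k = 0; k < nc; ++k) {
        mat Pg = pmat_g(lens(e) * rates(k));
        msg[(size_t)e * nc + k] = edge_msg(Pg, e, k);
        if (seen[p] == 0) down[(size_t)p * nc + k] = msg[(size_t)e * nc + k];
        else down[(size_t)p * nc + k] %= msg[(size_t)e * nc + k];
      }
      seen[p]++;
      if (seen[p] == (int)child_edges[p].size()) {
        rowvec m(npat, arma::fill::zeros);
        for (int k = 0; k < nc; ++k)
          m = arma::max(m, arma::max(down[(size_t)p * nc + k], 0));
        m.transform([](double x) { return x > 0.0 ? x : 1.0; });
        for (int k = 0; k < nc; ++k)
          down[(size_t)p * nc + k].each_row() /= m;
        rowvec ls = arma::log(m);
        for (int ce : child_edges[p]) ls += lsd[edge(ce, 1)];
        lsd[p] = ls;
      }
    }
  }

  double mix_site(double ls, double acc, int j) const {
    double a = acc > 0.0 ? ls + std::log(acc) : -arma::datum::inf;
    double b = log_pinv_term(j);
    if (b == -arma::datum::inf) return a;
    if (a == -arma::datum::inf) return b;
    double m = std::max(a, b);
    return m + std::log(std::exp(a - m) + std::exp(b - m));
  }

  // site log-likelihoods at the root (down_pass must be current)
  rowvec root_site_loglik() const {
    rowvec acc(npat, arma::fill::zeros);
    for (int k = 0; k < nc; ++k)
      acc += rw(k) * (pi.t() * down[(size_t)root * nc + k]);
    rowvec site(npat);
    for (int j = 0; j < npat; ++j)
      site(j) = mix_site(lsd[root](j), acc(j), j);
    return site;
  }

  double loglik_current() {
    down_pass();
    return arma::dot(w, root_site_loglik());
  }

  // --- per-edge likelihood profile in the eigenbasis -----------------------
  // L_k(j; t) = sum_m exp(lambda_m rate_k t) * A_k(m, j), where
  // A_k = (V' * (pi o E_k)) o (W * D_k); E_k = everything outside the edge,
  // evaluated at its parent endpoint; D_k = down partial of the child.
  // The nc category blocks are stacked (with their weights folded in) so a
  // line-search evaluation is a single (nc*ns) x npat matrix-vector product.
  struct EdgeProfile {
    mat A;                // (nc*ns) x npat stacked category blocks
    rowvec ls;            // per-pattern log scale (lsE + lsd[child])
  };

  // E matrices for edge e (out[p] times sibling messages), scaled; also
  // returns the E-side log-scale in lsE
  std::vector<mat> edge_E(int e, rowvec& lsE) {
    int p = edge(e, 0);
    std::vector<mat> Em(nc);
    for (int k = 0; k < nc; ++k) {
      mat t = out[(size_t)p * nc + k];
      for (int ce : child_edges[p])
        if (ce != e) t %= msg[(size_t)ce * nc + k];
      Em[k] = std::move(t);
    }
    rowvec m(npat, arma::fill::zeros);
    for (int k = 0; k < nc; ++k) m = arma::max(m, arma::max(Em[k], 0));
    m.transform([](double x) { return x > 0.0 ? x : 1.0; });
    for (int k = 0; k < nc; ++k) Em[k].each_row() /= m;
    lsE = lso[p] + arma::log(m);
    for (int ce : child_edges[p])
      if (ce != e) lsE += lsd[edge(ce, 1)];
    return Em;
  }

  EdgeProfile edge_profile(int e, std::vector<mat>& Em, const rowvec& lsE) {
    int c = edge(e, 1);
    EdgeProfile prof;
    prof.A.set_size(nc * ns, npat);
    mat Btip;
    if (c < ntip) Btip = Wg.cols(tipidx[c]);
    for (int k = 0; k < nc; ++k) {
      mat G = Em[k];
      G.each_col() %= pi * rw(k);
      mat VtG = V.t() * G;
      if (c < ntip)
        prof.A.rows(k * ns, (k + 1) * ns - 1) = VtG % Btip;
      else
        prof.A.rows(k * ns, (k + 1) * ns - 1) =
            VtG % (W * down[(size_t)c * nc + k]);
    }
    prof.ls = lsE + lsd[c];
    return prof;
  }

  double profile_loglik(const EdgeProfile& prof, double t) const {
    vec ex(nc * ns);
    for (int k = 0; k < nc; ++k)
      ex.subvec(k * ns, (k + 1) * ns - 1) = arma::exp(lam * (t * rates(k)));
    rowvec acc = ex.t() * prof.A;
    if (pinv <= 0.0) {
      acc.transform([](double x) { return x > 1e-300 ? x : 1e-300; });
      return arma::dot(w, prof.ls + arma::log(acc));
    }
    double ll = 0.0;
    for (int j = 0; j < npat; ++j)
      ll += w(j) * mix_site(prof.ls(j), std::max(acc(j), 0.0), j);
    return ll;
  }

  // Brent maximization of the edge profile on [lo, hi]
  double brent_edge(const EdgeProfile& prof, double t0, double lo, double hi,
                    double tol, int maxit, double* fout) {
    auto f = [&](double t) { return -profile_loglik(prof, t); };
    const double gold = 0.3819660112501051;
    double a = lo, b = hi;
    double x = std::min(std::max(t0, lo), hi);
    double wpt = x, v = x;
    double fx = f(x), fw = fx, fv = fx;
    double d = 0.0, ee = 0.0;
    for (int it = 0; it < maxit; ++it) {
      double xm = 0.5 * (a + b);
      double tol1 = tol * std::fabs(x) + 1e-8, tol2 = 2.0 * tol1;
      if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
      bool golden = true;
      if (std::fabs(ee) > tol1) {
        double r = (x - wpt) * (fx - fv);
        double q = (x - v) * (fx - fw);
        double p = (x - v) * q - (x - wpt) * r;
        q = 2.0 * (q - r);
        if (q > 0.0) p = -p;
        q = std::fabs(q);
        double etemp = ee;
        ee = d;
        if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
            p < q * (b - x)) {
          d = p / q;
          double u = x + d;
          if (u - a < tol2 || b - u < tol2)
            d = (xm - x >= 0 ? tol1 : -tol1);
          golden = false;
        }
      }
      if (golden) {
        ee = (x >= xm ? a - x : b - x);
        d = gold * ee;
      }
      double u = (std::fabs(d) >= tol1 ? x + d
                                       : x + (d >= 0 ? tol1 : -tol1));
      double fu = f(u);
      if (fu <= fx) {
        if (u >= x) a = x; else b = x;
        v = wpt; wpt = x; x = u;
        fv = fw; fw = fx; fx = fu;
      } else {
        if (u < x) a = u; else b = u;
        if (fu <= fw || wpt == x) {
          v = wpt; wpt = u; fv = fw; fw = fu;
        } else if (fu <= fv || v == x || v == wpt) {
          v = u; fv = fu;
        }
      }
    }
    *fout = -fx;
    return x;
  }

  // one optimization sweep over all edges; returns lnL after the sweep
  double sweep(double min_len, double max_len, double brent_tol,
               int brent_maxit) {
    down_pass();
    for (int k = 0; k < nc; ++k)
      out[(size_t)root * nc + k] = mat(ns, npat, arma::fill::ones);
    lso[root] = rowvec(npat, arma::fill::zeros);
    double cur = -arma::datum::inf;
    for (int e = E - 1; e >= 0; --e) {   // preorder: parents before children
      int c = edge(e, 1);
      rowvec lsE;
      std::vector<mat> Em = edge_E(e, lsE);
      EdgeProfile prof = edge_profile(e, Em, lsE);
      double f0 = profile_loglik(prof, lens(e));
      // warm bracket around the current value first; fall back to the full
      // range when the optimum presses against the narrow bracket
      double lo1 = std::max(min_len, lens(e) / 4.0);
      double hi1 = std::min(max_len, lens(e) * 4.0 + 0.02);
      double fstar;
      double tstar = brent_edge(prof, lens(e), lo1, hi1, brent_tol,
                                brent_maxit, &fstar);
      if ((tstar <= lo1 * 1.02 && lo1 > min_len * 1.5) ||
          (tstar >= hi1 * 0.98 && hi1 < max_len * 0.98)) {
        double f2;
        double t2 = brent_edge(prof, tstar, min_len, max_len, brent_tol,
                               brent_maxit, &f2);
        if (f2 > fstar) { fstar = f2; tstar = t2; }
      }
      if (fstar > f0) {
        lens(e) = tstar;
        cur = fstar;
        // refresh this edge's message so siblings processed later in the
        // sweep see the updated length (keeps the ascent exact)
        for (int k = 0; k < nc; ++k)
          msg[(size_t)e * nc + k] = edge_msg(pmat_g(lens(e) * rates(k)), e, k);
      } else {
        cur = f0;
      }
      if (c >= ntip) {   // push the out partial through the updated edge
        for (int k = 0; k < nc; ++k) {
          mat Pg = pmat_g(lens(e) * rates(k));
          out[(size_t)c * nc + k] = Pg.head_cols(ns) * Em[k];
        }
        lso[c] = lsE;
      }
    }
    return cur;
  }
};

}  // namespace

// [[Rcpp::export]]
List eng_loglik(IntegerMatrix edge, NumericVector lens, int nnode, int ntip,
                IntegerMatrix tip, NumericVector w, NumericMatrix V,
                NumericMatrix W, NumericVector lam, NumericVector pi,
                NumericVector rates, NumericVector rw, double pinv,
                IntegerVector cs) {
  Engine eng;
  eng.init(edge, lens, nnode, ntip, tip, w, V, W, lam, pi, rates, rw, pinv, cs);
  eng.down_pass();
  rowvec site = eng.root_site_loglik();
  double ll = arma::dot(eng.w, site);
  return List::create(_["loglik"] = ll,
                      _["site"] = NumericVector(site.begin(), site.end()));
}

// [[Rcpp::export]]
List eng_optim_bl(IntegerMatrix edge, NumericVector lens, int nnode, int ntip,
                  IntegerMatrix tip, NumericVector w, NumericMatrix V,
                  NumericMatrix W, NumericVector lam, NumericVector pi,
                  NumericVector rates, NumericVector rw, double pinv,
                  IntegerVector cs, double min_len, double max_len,
                  double tol, int max_passes, double brent_tol,
                  int brent_maxit) {
  Engine eng;
  eng.init(edge, lens, nnode, ntip, tip, w, V, W, lam, pi, rates, rw, pinv, cs);
  double cur = eng.loglik_current();
  int pass = 0;
  bool converged = false;
  for (pass = 1; pass <= max_passes; ++pass) {
    double before = cur;
    cur = eng.sweep(min_len, max_len, brent_tol, brent_maxit);
    if (cur - before < tol) { converged = true; break; }
  }
  eng.down_pass();
  rowvec site = eng.root_site_loglik();
  double ll = arma::dot(eng.w, site);
  return List::create(
      _["lens"] = NumericVector(eng.lens.begin(), eng.lens.end()),
      _["loglik"] = ll, _["passes"] = std::min(pass, max_passes),
      _["converged"] = converged,
      _["site"] = NumericVector(site.begin(), site.end()));
}
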