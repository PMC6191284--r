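// Felsenstein pruning likelihood for a codon substitution model with
// branch-specific dN/dS classes (Muse-Gaut style rates over the 61 sense
// codons).  The rate matrix of each class is reversible with respect to the
// F3x4 product frequencies, so it is symmetrized and eigendecomposed; the
// decomposition depends only on (kappa, omega) and is cached R-side across
// the many likelihood evaluations that move only branch lengths.
// Per-pattern scaling guards against underflow.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const int NS = 61;

// Eigendecomposition of the unit-mean-rate class matrix.
// fac(i,j): position-specific target-nucleotide frequency of the single-nt
// change i->j (0 if not a single-nt change); type: 1 syn ts, 2 syn tv,
// 3 nonsyn ts, 4 nonsyn tv.
static void class_eigen(const arma::imat& type, const arma::mat& fac,
                        const arma::vec& pi, double kappa, double omega,
                        arma::vec& val, arma::mat& left, arma::mat& right) {
  arma::mat Q(NS, NS, arma::fill::zeros);
  for (int i = 0; i < NS; ++i) {
    for (int j = 0; j < NS; ++j) {
      int t = type(i, j);
      if (t == 0) continue;
      double r = fac(i, j);
      if (t == 1 || t == 3) r *= kappa;        // transition
      if (t == 3 || t == 4) r *= omega;        // nonsynonymous
      Q(i, j) = r;
    }
  }
  arma::vec rs = arma::sum(Q, 1);
  double mean_rate = arma::dot(pi, rs);
  Q /= mean_rate;                              // one expected sub/site/unit
  rs /= mean_rate;
  Q.diag() = -rs;
  arma::vec d = arma::sqrt(pi);
  arma::mat B = arma::diagmat(d) * Q * arma::diagmat(1.0 / d);
  B = 0.5 * (B + B.t());
  arma::mat U;
  arma::eig_sym(val, U, B);
  left = arma::diagmat(1.0 / d) * U;
  right = U.t() * arma::diagmat(d);
}

// Precompute eigensystems for each dN/dS class.
// [[Rcpp::export]]
List codon_eigens(const arma::imat& type, const arma::mat& fac,
                  const arma::vec& pi, double kappa,
                  const arma::vec& omegas) {
  int ncls = omegas.n_elem;
  List out(ncls);
  for (int c = 0; c < ncls; ++c) {
    arma::vec val;
    arma::mat left, right;
    class_eigen(type, fac, pi, kappa, omegas(c), val, left, right);
    out[c] = List::create(Named("val") = val, Named("left") = left,
                          Named("right") = right);
  }
  return out;
}

static arma::mat pmat(const arma::vec& val, const arma::mat& left,
                      const arma::mat& right, double t) {
  arma::mat P = left * arma::diagmat(arma::exp(val * t)) * right;
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

// Log-likelihood of the codon alignment patterns under the branch-class
// model.  edge: (parent, child) 1-based node ids in postorder; tips are
// nodes 1..n_tip.  tip_states: n_tip x npat, 1-based sense-codon states,
// 0 = missing.  edge_class: 1-based index into the eigens list.
// [[Rcpp::export]]
double codon_lnL(const arma::imat& edge, const arma::vec& edge_len,
                 const arma::ivec& edge_class, List eigens,
                 const arma::vec& pi, const arma::imat& tip_states,
                 const arma::vec& weights, int n_tip, int n_node) {
  const int npat = tip_states.n_cols;
  const int ncls = eigens.size();
  std::vector<arma::vec> vals(ncls);
  std::vector<arma::mat> lefts(ncls), rights(ncls);
  for (int c = 0; c < ncls; ++c) {
    List e = eigens[c];
    vals[c] = as<arma::vec>(e["val"]);
    lefts[c] = as<arma::mat>(e["left"]);
    rights[c] = as<arma::mat>(e["right"]);
  }
  std::vector<arma::mat> clv(n_node + 1);
  std::vector<bool> seen(n_node + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int pa = edge(e, 0), ch = edge(e, 1);
    int c = edge_class(e) - 1;
    arma::mat P = pmat(vals[c], lefts[c], rights[c], edge_len(e));
    arma::mat contrib(NS, npat);
    if (ch <= n_tip) {
      for (int s = 0; s < npat; ++s) {
        int st = tip_states(ch - 1, s);
        if (st == 0) {
          contrib.col(s).ones();
        } else {
          contrib.col(s) = P.col(st - 1);
        }
      }
    } else {
      contrib = P * clv[ch];
      arma::rowvec m = arma::max(contrib, 0);
      m.elem(arma::find(m <= 0)).ones();
      contrib.each_row() /= m;
      logscale += arma::log(m);
    }
    if (!seen[pa]) {
      clv[pa] = contrib;
      seen[pa] = true;
    } else {
      clv[pa] %= contrib;
    }
  }
  int root = edge(edge.n_rows - 1, 0);
  arma::rowvec site_lik = pi.t() * clv[root];
  double lnL = 0.0;
  for (int s = 0; s < npat; ++s) {
    double l = site_lik(s);
    if (l <= 0 || !std::isfinite(l)) {
      return -std::numeric_limits<double>::infinity();
    }
    lnL += weights(s) * (std::log(l) + logscale(s));
  }
  return lnL;
}
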