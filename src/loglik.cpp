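// Partitioned branch-site mixture likelihood: MG94xREV rate matrices,
// symmetric-transform matrix exponentials, and Felsenstein pruning with
// per-branch mixture transition matrices. Kept in compiled code because a
// 61-state pruning pass sits inside the optimizer's inner loop.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

using namespace arma;

// Unscaled MG94xREV generator for one omega. codon_nuc is nstate x 3 with
// values 1..4 (A,C,G,T); aa_idx codes the amino acid of each sense codon.
static mat build_Q(const vec& exch, const vec& pi, const mat& posfreq,
                   const imat& codon_nuc, const ivec& aa_idx, double omega) {
  const int n = codon_nuc.n_rows;
  // symmetric 4x4 exchangeability matrix, GT fixed at 1
  mat r(4, 4, fill::zeros);
  r(0, 1) = exch(0); r(0, 2) = exch(1); r(0, 3) = exch(2);
  r(1, 2) = exch(3); r(1, 3) = exch(4); r(2, 3) = 1.0;
  r = r + r.t();

  mat Q(n, n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      int diffpos = -1, ndiff = 0;
      for (int p = 0; p < 3; ++p) {
        if (codon_nuc(i, p) != codon_nuc(j, p)) { diffpos = p; ++ndiff; }
      }
      if (ndiff != 1) continue;
      const int a = codon_nuc(i, diffpos) - 1;
      const int b = codon_nuc(j, diffpos) - 1;
      double rate = r(a, b) * posfreq(diffpos, b);
      if (aa_idx(i) != aa_idx(j)) rate *= omega;
      Q(i, j) = rate;
    }
  }
  Q.diag() = -sum(Q, 1);
  (void)pi; // stationarity is implied by the MG94 product form
  return Q;
}

struct Eig { mat V; vec lambda; };

// Symmetric-similarity eigendecomposition of a pi-reversible generator.
static Eig reversible_eig(const mat& Q, const vec& sqrt_pi) {
  mat S = Q;
  S.each_col() %= sqrt_pi;
  S.each_row() /= sqrt_pi.t();
  S = 0.5 * (S + S.t());
  Eig e;
  eig_sym(e.lambda, e.V, S);
  return e;
}

static mat transition_from_eig(const Eig& e, const vec& sqrt_pi, double t) {
  mat P = e.V * diagmat(exp(e.lambda * t)) * e.V.t();
  P.each_col() /= sqrt_pi;
  P.each_row() %= sqrt_pi.t();
  P.elem(find(P < 0)).zeros();
  P.each_col() /= sum(P, 1);  // renormalise rows
  return P;
}

// Per-edge mixture transition matrices for the branch-site process.
static std::vector<mat> edge_mixture_matrices(
    const vec& edge_length, const ivec& edge_group,
    const Rcpp::List& group_omegas, const Rcpp::List& group_weights,
    const vec& exch, const vec& pi, const mat& posfreq,
    const imat& codon_nuc, const ivec& aa_idx) {

  const vec sqrt_pi = sqrt(pi);
  const mat Q1 = build_Q(exch, pi, posfreq, codon_nuc, aa_idx, 1.0);
  const double scale = -dot(pi, Q1.diag());
  if (!(scale > 0)) Rcpp::stop("degenerate model: neutral rate constant is not positive");

  // eigendecompositions cached by omega value (omega = 1 is shared by all
  // partitions, and merged foregrounds repeat omegas across groups)
  std::map<double, Eig> cache;
  auto eig_for = [&](double omega) -> const Eig& {
    auto it = cache.find(omega);
    if (it == cache.end()) {
      mat Q = build_Q(exch, pi, posfreq, codon_nuc, aa_idx, omega) / scale;
      it = cache.emplace(omega, reversible_eig(Q, sqrt_pi)).first;
    }
    return it->second;
  };

  const int nedge = edge_length.n_elem;
  std::vector<mat> P(nedge);
  for (int k = 0; k < nedge; ++k) {
    const int g = edge_group(k) - 1;
    const vec om = Rcpp::as<vec>(group_omegas[g]);
    const vec w  = Rcpp::as<vec>(group_weights[g]);
    mat Pk(pi.n_elem, pi.n_elem, fill::zeros);
    for (unsigned c = 0; c < om.n_elem; ++c) {
      if (w(c) <= 0) continue;
      Pk += w(c) * transition_from_eig(eig_for(om(c)), sqrt_pi, edge_length(k));
    }
    P[k] = Pk;
  }
  return P;
}

// [[Rcpp::export]]
Rcpp::List cpp_partitioned_loglik(
    const arma::cube& tipcond,      // nstate x npat x ntip
    const arma::vec& counts,        // npat
    const arma::imat& edge,         // nedge x 2: parent, child (1-based, postorder)
    const arma::vec& edge_length,
    const arma::ivec& edge_group,   // 1-based group per edge
    const int n_node_total,
    const int root,
    const Rcpp::List& group_omegas,
    const Rcpp::List& group_weights,
    const arma::vec& exch,
    const arma::vec& pi,
    const arma::mat& posfreq,
    const arma::imat& codon_nuc,
    const arma::ivec& aa_idx) {

  const int nstate = tipcond.n_rows;
  const int npat = tipcond.n_cols;
  const int ntip = tipcond.n_slices;
  const int nedge = edge.n_rows;

  std::vector<mat> P = edge_mixture_matrices(
      edge_length, edge_group, group_omegas, group_weights,
      exch, pi, posfreq, codon_nuc, aa_idx);

  std::vector<mat> cond(n_node_total);
  std::vector<bool> seen(n_node_total, false);
  rowvec logscale(npat, fill::zeros);

  for (int k = 0; k < nedge; ++k) {
    const int pa = edge(k, 0) - 1;
    const int ch = edge(k, 1) - 1;
    mat msg;
    if (ch < ntip) {
      msg = P[k] * tipcond.slice(ch);
    } else {
      msg = P[k] * cond[ch];
    }
    if (!seen[pa]) { cond[pa] = msg; seen[pa] = true; }
    else cond[pa] %= msg;
    // per-pattern rescale to dodge underflow on deep trees
    rowvec m = max(cond[pa], 0);
    for (int j = 0; j < npat; ++j) {
      if (m(j) > 0 && m(j) < 1e-200) {
        cond[pa].col(j) /= m(j);
        logscale(j) += std::log(m(j));
      }
    }
  }

  rowvec site_lik = pi.t() * cond[root - 1];
  rowvec pat_ll(npat);
  for (int j = 0; j < npat; ++j) {
    pat_ll(j) = (site_lik(j) > 0 ? std::log(site_lik(j)) : -datum::inf) + logscale(j);
  }
  const double total = dot(counts, pat_ll.t());
  (void)nstate;
  return Rcpp::List::create(Rcpp::Named("loglik") = total,
                            Rcpp::Named("pattern_loglik") =
                                Rcpp::NumericVector(pat_ll.begin(), pat_ll.end()));
}

// Per-edge, per-category transition matrices (used by the simulator so the
// generative process and the likelihood share one matrix construction).
// [[Rcpp::export]]
Rcpp::List cpp_category_matrices(
    const arma::vec& edge_length,
    const arma::ivec& edge_group,
    const Rcpp::List& group_omegas,
    const arma::vec& exch,
    const arma::vec& pi,
    const arma::mat& posfreq,
    const arma::imat& codon_nuc,
    const arma::ivec& aa_idx) {

  const vec sqrt_pi = sqrt(pi);
  const mat Q1 = build_Q(exch, pi, posfreq, codon_nuc, aa_idx, 1.0);
  const double scale = -dot(pi, Q1.diag());
  std::map<double, Eig> cache;
  auto eig_for = [&](double omega) -> const Eig& {
    auto it = cache.find(omega);
    if (it == cache.end()) {
      mat Q = build_Q(exch, pi, posfreq, codon_nuc, aa_idx, omega) / scale;
      it = cache.emplace(omega, reversible_eig(Q, sqrt_pi)).first;
    }
    return it->second;
  };

  const int nedge = edge_length.n_elem;
  Rcpp::List out(nedge);
  for (int k = 0; k < nedge; ++k) {
    const int g = edge_group(k) - 1;
    const vec om = Rcpp::as<vec>(group_omegas[g]);
    Rcpp::List cats(om.n_elem);
    for (unsigned c = 0; c < om.n_elem; ++c) {
      cats[c] = Rcpp::wrap(transition_from_eig(eig_for(om(c)), sqrt_pi,
                                               edge_length(k)));
    }
    out[k] = cats;
  }
  return out;
}
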