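// Fisher-scoring (IGLS) maximum-likelihood fitter for random-intercept /
// random-slope growth models, optionally joined with a per-individual distal
// outcome that carries no occasion-level residual.
//
// Model, per individual j with design A_j (n x q):
//   y_j ~ N(A_j beta, V_j),  V_j = A_j Omega A_j' + sige2 * D
// where D is the identity over height rows and zero on the outcome row.
// The variance parameters theta = (vech(Omega), sige2) enter V_j linearly,
// so Fisher scoring on theta alternated with GLS for beta is exactly the
// iterative generalised least squares scheme classically used for Gaussian
// multilevel models, and converges to the ML solution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Basis {
  // entry list of the symmetric derivative matrix dV/dtheta_k restricted to
  // Omega coordinates: one (a,a) entry, or the pair (a,b),(b,a)
  unsigned a, b;
};

// tr(B * E_k) for symmetric B
inline double tr_BE(const mat& B, const Basis& e) {
  return (e.a == e.b) ? B(e.a, e.a) : 2.0 * B(e.a, e.b);
}
// v' E_k v
inline double quad_E(const vec& v, const Basis& e) {
  return (e.a == e.b) ? v(e.a) * v(e.a) : 2.0 * v(e.a) * v(e.b);
}
// tr(B E_k B E_l) for symmetric B; E_k = sum of its unit entries
inline double tr_BEBE(const mat& B, const Basis& k, const Basis& l) {
  const unsigned kr[2] = {k.a, k.b}, kc[2] = {k.b, k.a};
  const unsigned lr[2] = {l.a, l.b}, lc[2] = {l.b, l.a};
  const int nk = (k.a == k.b) ? 1 : 2, nl = (l.a == l.b) ? 1 : 2;
  double s = 0.0;
  for (int i = 0; i < nk; ++i)
    for (int m = 0; m < nl; ++m)
      s += B(kc[i], lr[m]) * B(lc[m], kr[i]);
  return s;
}

// Assemble per-individual design: height rows (1, age[, 0]), outcome row (0,0,1)
inline void make_design(mat& A, const rowvec& ages, bool joint) {
  const unsigned I = ages.n_elem;
  A.zeros();
  for (unsigned i = 0; i < I; ++i) {
    A(i, 0) = 1.0;
    A(i, 1) = ages(i);
  }
  if (joint) A(I, 2) = 1.0;
}

struct EvalResult {
  bool ok = false;
  double loglik = -datum::inf;
  vec beta;
  mat beta_cov;       // (sum_j A' Vinv A)^{-1}
  vec score;          // d loglik / d theta at GLS beta
  mat info;           // expected information for theta
};

// One full pass: GLS beta, loglik, score and expected information for theta.
EvalResult eval_theta(const mat& ages, const mat& heights, const vec& bp,
                      bool joint, const vec& theta,
                      const std::vector<Basis>& basis) {
  EvalResult out;
  const unsigned J = ages.n_rows, I = ages.n_cols;
  const unsigned q = joint ? 3 : 2;
  const unsigned n = joint ? I + 1 : I;
  const unsigned nv = basis.size();      // vech(Omega) length
  const unsigned p = nv + 1;             // + sige2

  const double sige2 = theta(nv);
  if (!(sige2 > 0.0) || !theta.is_finite()) return out;

  mat Omega(q, q);
  for (unsigned k = 0; k < nv; ++k) {
    Omega(basis[k].a, basis[k].b) = theta(k);
    Omega(basis[k].b, basis[k].a) = theta(k);
  }

  mat A(n, q);
  vec y(n), r(n), w(n), aa(q);
  mat XtVX(q, q, fill::zeros);
  vec XtVy(q, fill::zeros);
  cube Vinv_store(n, n, J);
  double logdet_sum = 0.0;

  for (unsigned j = 0; j < J; ++j) {
    make_design(A, ages.row(j), joint);
    mat V = symmatu(A * Omega * A.t());
    for (unsigned i = 0; i < I; ++i) V(i, i) += sige2;
    mat L;
    if (!chol(L, V, "lower")) return out;
    double ld = 0.0;
    for (unsigned i = 0; i < n; ++i) ld += std::log(L(i, i));
    logdet_sum += 2.0 * ld;
    mat Vinv = inv_sympd(V);
    Vinv_store.slice(j) = Vinv;
    mat M = Vinv * A;
    for (unsigned i = 0; i < I; ++i) y(i) = heights(j, i);
    if (joint) y(I) = bp(j);
    XtVX += A.t() * M;
    XtVy += M.t() * y;
  }

  mat XtVX_inv;
  if (!inv_sympd(XtVX_inv, symmatu(XtVX))) return out;
  vec beta = XtVX_inv * XtVy;

  vec score(p, fill::zeros);
  mat info(p, p, fill::zeros);
  double quad_sum = 0.0;

  for (unsigned j = 0; j < J; ++j) {
    make_design(A, ages.row(j), joint);
    for (unsigned i = 0; i < I; ++i) y(i) = heights(j, i);
    if (joint) y(I) = bp(j);
    const mat& Vinv = Vinv_store.slice(j);
    r = y - A * beta;
    w = Vinv * r;
    quad_sum += dot(r, w);

    mat M = Vinv * A;          // n x q
    mat B = A.t() * M;         // q x q, symmetric
    aa = M.t() * r;            // A' Vinv r

    // residual-block quantities (rows 0..I-1 carry sige2)
    double d1 = 0.0, d2 = 0.0, wDw = 0.0;
    for (unsigned i = 0; i < I; ++i) {
      d1 += Vinv(i, i);
      wDw += w(i) * w(i);
      for (unsigned l = 0; l < I; ++l) d2 += Vinv(i, l) * Vinv(i, l);
    }
    // C = M' D M  (cross term between Omega params and sige2)
    mat C = M.rows(0, I - 1).t() * M.rows(0, I - 1);

    for (unsigned k = 0; k < nv; ++k) {
      score(k) += -0.5 * (tr_BE(B, basis[k]) - quad_E(aa, basis[k]));
      for (unsigned l = k; l < nv; ++l)
        info(k, l) += 0.5 * tr_BEBE(B, basis[k], basis[l]);
      info(k, nv) += 0.5 * tr_BE(C, basis[k]);
    }
    score(nv) += -0.5 * (d1 - wDw);
    info(nv, nv) += 0.5 * d2;
  }
  info = symmatu(info);

  out.ok = true;
  out.loglik = -0.5 * (double(J * n) * std::log(2.0 * datum::pi) +
                       logdet_sum + quad_sum);
  out.beta = beta;
  out.beta_cov = XtVX_inv;
  out.score = score;
  out.info = info;
  return out;
}

std::vector<Basis> make_basis(unsigned q) {
  std::vector<Basis> basis;
  for (unsigned b = 0; b < q; ++b)
    for (unsigned a = b; a < q; ++a) basis.push_back({a, b});
  return basis;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_fit_lmm(const arma::mat& ages, const arma::mat& heights,
                       const arma::vec& bp, bool joint,
                       const arma::mat& Omega0, double sige2_0,
                       int max_iter, double tol) {
  const unsigned q = joint ? 3 : 2;
  std::vector<Basis> basis = make_basis(q);
  const unsigned nv = basis.size(), p = nv + 1;

  vec theta(p);
  for (unsigned k = 0; k < nv; ++k) theta(k) = Omega0(basis[k].a, basis[k].b);
  theta(nv) = sige2_0;

  EvalResult cur = eval_theta(ages, heights, bp, joint, theta, basis);
  if (!cur.ok)
    Rcpp::stop("initial variance parameters give a non-positive-definite covariance");

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    vec delta;
    bool solved = solve(delta, cur.info, cur.score, solve_opts::likely_sympd);
    if (!solved)
      solved = solve(delta, cur.info + 1e-8 * eye(p, p), cur.score);
    if (!solved) break;

    double step = 1.0;
    EvalResult nxt;
    bool accepted = false;
    for (int h = 0; h < 40; ++h) {
      nxt = eval_theta(ages, heights, bp, joint, theta + step * delta, basis);
      if (nxt.ok && nxt.loglik >= cur.loglik - 1e-10) {
        accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) break;
    theta += step * delta;
    double change = std::fabs(nxt.loglik - cur.loglik);
    cur = nxt;
    if (change < tol * (std::fabs(cur.loglik) + 1.0)) {
      converged = true;
      break;
    }
  }

  mat Omega(q, q);
  for (unsigned k = 0; k < nv; ++k) {
    Omega(basis[k].a, basis[k].b) = theta(k);
    Omega(basis[k].b, basis[k].a) = theta(k);
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = cur.beta,
      Rcpp::Named("beta_cov") = cur.beta_cov,
      Rcpp::Named("omega") = Omega,
      Rcpp::Named("sige2") = theta(nv),
      Rcpp::Named("theta") = theta,
      Rcpp::Named("theta_info") = cur.info,
      Rcpp::Named("loglik") = cur.loglik,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = iter);
}

// BLUPs u_hat_j = Omega A_j' V_j^{-1} (y_j - A_j beta) at given parameters.
// [[Rcpp::export]]
arma::mat cpp_blups(const arma::mat& ages, const arma::mat& heights,
                    const arma::vec& bp, bool joint, const arma::vec& beta,
                    const arma::mat& Omega, double sige2) {
  const unsigned J = ages.n_rows, I = ages.n_cols;
  const unsigned q = joint ? 3 : 2;
  const unsigned n = joint ? I + 1 : I;
  mat A(n, q);
  vec y(n);
  mat u(J, q);
  for (unsigned j = 0; j < J; ++j) {
    make_design(A, ages.row(j), joint);
    mat V = symmatu(A * Omega * A.t());
    for (unsigned i = 0; i < I; ++i) V(i, i) += sige2;
    for (unsigned i = 0; i < I; ++i) y(i) = heights(j, i);
    if (joint) y(I) = bp(j);
    vec w;
    if (!solve(w, V, y - A * beta, solve_opts::likely_sympd))
      Rcpp::stop("singular marginal covariance for individual %d", j + 1);
    u.row(j) = (Omega * (A.t() * w)).t();
  }
  return u;
}

// Marginal Gaussian log-likelihood at fixed parameters (used for constrained
// evaluations and decomposition checks).
// [[Rcpp::export]]
double cpp_lmm_loglik(const arma::mat& ages, const arma::mat& heights,
                      const arma::vec& bp, bool joint, const arma::vec& beta,
                      const arma::mat& Omega, double sige2) {
  const unsigned J = ages.n_rows, I = ages.n_cols;
  const unsigned q = joint ? 3 : 2;
  const unsigned n = joint ? I + 1 : I;
  mat A(n, q);
  vec y(n);
  double ll = 0.0;
  for (unsigned j = 0; j < J; ++j) {
    make_design(A, ages.row(j), joint);
    mat V = symmatu(A * Omega * A.t());
    for (unsigned i = 0; i < I; ++i) V(i, i) += sige2;
    for (unsigned i = 0; i < I; ++i) y(i) = heights(j, i);
    if (joint) y(I) = bp(j);
    mat L;
    if (!chol(L, V, "lower")) Rcpp::stop("non-positive-definite covariance");
    vec r = y - A * beta;
    vec z = solve(trimatl(L), r);
    double ld = 0.0;
    for (unsigned i = 0; i < n; ++i) ld += std::log(L(i, i));
    ll += -0.5 * (double(n) * std::log(2.0 * datum::pi) + 2.0 * ld + dot(z, z));
  }
  return ll;
}
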