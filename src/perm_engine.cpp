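#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Freedman-Lane max-|t| permutation for per-voxel OLS, with Huh-Jhun
// exchangeable residuals.
//
// The per-voxel design is [C | voxel columns | interaction products].
// For the focal column, the outcome and the column are residualised on the
// remaining (nuisance) columns once per voxel, then projected onto an
// orthonormal basis of the nuisance null space, where the residual
// coordinates are exactly exchangeable under Gaussian errors (plain
// Freedman-Lane permutes raw residuals, whose uneven leverage shrinkage
// makes the permutation null slightly light-tailed in structured designs).
// Each permutation shuffles the projected outcome coordinates; the
// full-model focal t-statistic reduces to simple-regression algebra in
// that space. The maximum |t| over voxels is recorded per permutation.
//
// Y     : n x V outcome matrix (n x 1 allowed: the same outcome, e.g. a
//         cognitive slope, reused at every voxel)
// Cmat  : n x q shared scalar design (intercept, global terms, covariates)
// vox   : list of n x V voxel-level predictor matrices
// inter : 2 x k matrix of 1-based indices into vox giving product terms
// term  : 1-based focal column in the full design
// perms : m x B matrix of 1-based permutation indices; m = n - (p - 1)
//         (nuisance null-space dimension) for scheme 1, else n
// scheme: 0 = raw outcome permutation (exact under joint independence),
//         1 = Huh-Jhun exchangeable residuals,
//         2 = classic Freedman-Lane residual permutation
// [[Rcpp::export]]
Rcpp::List fl_max_t_cpp(const arma::mat& Y, const arma::mat& Cmat,
                        const Rcpp::List& vox, const arma::imat& inter,
                        const int term, const arma::umat& perms,
                        const int scheme) {
  const uword n = Cmat.n_rows;
  const uword q = Cmat.n_cols;
  const uword nv = vox.size();
  const uword ni = inter.n_cols;
  const uword p = q + nv + ni;
  const uword B = perms.n_cols;

  std::vector<mat> VX(nv);
  uword V = (Y.n_cols > 1) ? Y.n_cols : 0;
  for (uword m = 0; m < nv; ++m) {
    VX[m] = Rcpp::as<mat>(vox[m]);
    V = std::max(V, VX[m].n_cols);
  }
  if (V == 0) V = 1;
  if (p >= n) Rcpp::stop("design has as many columns as subjects");

  const double df = static_cast<double>(n - p);
  vec t_obs(V); t_obs.fill(datum::nan);
  vec max_t(B, fill::zeros);
  umat perm0 = perms - 1;  // to 0-based

  mat X(n, p);
  X.cols(0, q - 1) = Cmat;

  for (uword v = 0; v < V; ++v) {
    for (uword m = 0; m < nv; ++m) X.col(q + m) = VX[m].col(v);
    for (uword k = 0; k < ni; ++k)
      X.col(q + nv + k) = VX[inter(0, k) - 1].col(v) % VX[inter(1, k) - 1].col(v);
    vec y = (Y.n_cols > 1) ? Y.col(v) : Y.col(0);

    uvec keep = regspace<uvec>(0, p - 1);
    keep.shed_row(term - 1);
    mat Z = X.cols(keep);
    vec x = X.col(term - 1);

    mat Qfull, Rfull;
    if (!qr(Qfull, Rfull, Z)) continue;
    vec dR = Rfull.diag();
    vec rdiag = abs(dR.head(p - 1));
    double rmax = rdiag.max();
    if (rmax <= 0 || rdiag.min() < 1e-10 * rmax) continue;
    mat Qz = Qfull.cols(0, p - 2);      // nuisance column space, n x (p-1)
    mat Qn = Qfull.cols(p - 1, n - 1);  // its complement, n x m

    vec et = Qn.t() * y;   // exchangeable outcome coordinates
    vec ext = Qn.t() * x;  // focal column in the same space
    double exn = dot(ext, ext);
    double xn = dot(x, x);
    if (exn < 1e-12 * (xn > 0 ? xn : 1.0)) continue;
    double eyn = dot(et, et);  // ||residualised y||^2, permutation-invariant

    double b = dot(ext, et) / exn;
    double rss = eyn - b * b * exn;
    if (rss < 0) rss = 0;
    double se = std::sqrt(rss / df / exn);
    t_obs(v) = (se > 0) ? b / se : (b == 0 ? 0.0 : datum::inf);

    if (scheme == 1) {
      // Huh-Jhun: permute the null-space coordinates directly
      for (uword j = 0; j < B; ++j) {
        double num = dot(ext, et.elem(perm0.col(j)));
        double bb = num / exn;
        double r2 = eyn - bb * bb * exn;
        if (r2 < 1e-300) r2 = 1e-300;
        double tt = std::fabs(bb) / std::sqrt(r2 / df / exn);
        if (tt > max_t(j)) max_t(j) = tt;
      }
    } else {
      // permute an n-vector and refit the full model:
      // raw outcome (scheme 0) or its nuisance residuals (scheme 2)
      vec ex = x - Qz * (Qz.t() * x);
      vec base = y;
      if (scheme == 2) base = y - Qz * (Qz.t() * y);
      double basen = dot(base, base);
      for (uword j = 0; j < B; ++j) {
        vec ys = base.elem(perm0.col(j));
        double num = dot(ex, ys);
        vec qy = Qz.t() * ys;
        double rz = basen - dot(qy, qy);  // ||ys||^2 is permutation-invariant
        double bb = num / exn;
        double r2 = rz - bb * bb * exn;
        if (r2 < 1e-300) r2 = 1e-300;
        double tt = std::fabs(bb) / std::sqrt(r2 / df / exn);
        if (tt > max_t(j)) max_t(j) = tt;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("t_obs") = t_obs,
                            Rcpp::Named("max_t") = max_t,
                            Rcpp::Named("df") = df);
}
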