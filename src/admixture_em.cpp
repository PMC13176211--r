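#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Maximum-likelihood admixture fit for the binomial model
//   g_ij ~ Binomial(2, theta_ij), theta = Q F
// over missing-masked entries. G holds dosages 0/1/2 with -1 for
// missing; Q is n x K (rows sum to 1), F is K x L with entries kept in
// [fmin, 1 - fmin] so the likelihood stays finite.
//
// The EM map has closed-form updates; because plain EM crawls near the
// optimum, iterations are accelerated with the SQUAREM (SqS3) scheme,
// safeguarded so the reported log-likelihood trace is non-decreasing:
// an accelerated proposal is only accepted when it does not fall below
// the plain double EM step it replaces.

struct Model {
  mat G1, G2;   // masked alt / ref allele copies (n x L)
  vec mrow;     // called loci per sample
  double fmin;

  double loglik(const mat& Q, const mat& F) const {
    mat Theta = clamp(Q * F, 1e-12, 1.0 - 1e-12);
    return accu(G1 % log(Theta) + G2 % log1p(-Theta));
  }

  void em_step(mat& Q, mat& F) const {
    const uword K = Q.n_cols;
    mat Theta = clamp(Q * F, 1e-12, 1.0 - 1e-12);
    mat A = G1 / Theta;
    mat B = G2 / (1.0 - Theta);
    mat Qn = Q % (A * F.t() + B * (1.0 - F).t());
    Qn.each_col() /= (2.0 * mrow);
    vec rs = sum(Qn, 1);
    for (uword i = 0; i < Qn.n_rows; ++i)
      if (rs(i) <= 0) { Qn.row(i).fill(1.0 / K); rs(i) = 1.0; }
    Qn.each_col() /= rs;
    mat num = F % (Q.t() * A);
    mat den = (1.0 - F) % (Q.t() * B);
    mat tot = num + den;
    tot.elem(find(tot <= 0)).fill(1.0);
    F = clamp(num / tot, fmin, 1.0 - fmin);
    Q = Qn;
  }

  void project(mat& Q, mat& F) const {
    Q.transform([](double v) { return v < 0 ? 0.0 : v; });
    vec rs = sum(Q, 1);
    for (uword i = 0; i < Q.n_rows; ++i)
      if (rs(i) <= 0) { Q.row(i).fill(1.0 / Q.n_cols); rs(i) = 1.0; }
    Q.each_col() /= rs;
    F = clamp(F, fmin, 1.0 - fmin);
  }
};

// [[Rcpp::export]]
Rcpp::List admixture_em_cpp(const arma::imat& G, arma::mat Q, arma::mat F,
                            double tol, int max_iter, double fmin,
                            bool accelerate = true) {
  const uword n = G.n_rows, L = G.n_cols;
  Model mod;
  mod.G1.set_size(n, L);
  mod.G2.set_size(n, L);
  for (uword j = 0; j < L; ++j)
    for (uword i = 0; i < n; ++i) {
      int g = G(i, j);
      if (g < 0) { mod.G1(i, j) = 0.0; mod.G2(i, j) = 0.0; }
      else       { mod.G1(i, j) = (double)g; mod.G2(i, j) = 2.0 - g; }
    }
  mod.mrow = sum(mod.G1 + mod.G2, 1) / 2.0;
  mod.mrow.elem(find(mod.mrow <= 0)).fill(1e-9);
  mod.fmin = fmin;

  F = clamp(F, fmin, 1.0 - fmin);
  std::vector<double> trace;
  double ll = mod.loglik(Q, F);
  trace.push_back(ll);
  bool converged = false;

  for (int it = 1; it <= max_iter; ++it) {
    double ll_new;
    if (!accelerate) {
      mod.em_step(Q, F);
      ll_new = mod.loglik(Q, F);
    } else {
      mat Q1 = Q, F1 = F;
      mod.em_step(Q1, F1);
      mat Q2 = Q1, F2 = F1;
      mod.em_step(Q2, F2);
      mat rQ = Q1 - Q, rF = F1 - F;
      mat vQ = (Q2 - Q1) - rQ, vF = (F2 - F1) - rF;
      double rn = accu(rQ % rQ) + accu(rF % rF);
      double vn = accu(vQ % vQ) + accu(vF % vF);
      double ll2 = mod.loglik(Q2, F2);
      ll_new = ll2;
      mat Qa, Fa;
      bool accepted = false;
      if (vn > 0) {
        double alpha = -std::sqrt(rn / vn);
        if (alpha > -1.0) alpha = -1.0;
        Qa = Q - 2.0 * alpha * rQ + alpha * alpha * vQ;
        Fa = F - 2.0 * alpha * rF + alpha * alpha * vF;
        mod.project(Qa, Fa);
        mod.em_step(Qa, Fa);   // stabilising EM step
        double lla = mod.loglik(Qa, Fa);
        if (std::isfinite(lla) && lla >= ll2) {
          ll_new = lla;
          accepted = true;
        }
      }
      if (accepted) { Q = Qa; F = Fa; }
      else          { Q = Q2; F = F2; }
    }
    trace.push_back(ll_new);
    if (ll_new - ll < tol) { converged = true; ll = ll_new; break; }
    ll = ll_new;
  }

  return Rcpp::List::create(
    Rcpp::Named("Q") = Q,
    Rcpp::Named("F") = F,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("iterations") = (int)trace.size() - 1,
    Rcpp::Named("converged") = converged);
}
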