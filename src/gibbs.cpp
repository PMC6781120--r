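#include <Rcpp.h>
using namespace Rcpp;

// Single-chain Gibbs sampler for a linear mixed model with scalar random
// terms and group-wise heterogeneous residual variances.
//
// Location parameters are updated one equation at a time (Gauss-Seidel with
// noise); each random-term variance and each group residual variance is
// then drawn from its scaled-inverse-chi-square full conditional under flat
// priors. The fixed block (the first n_fixed equations) carries no prior.
//
// W: records x equations design (CSC slots), y: response,
// rec_group: 0-based residual group per record,
// terms: for each random term, 0-based start column, size q, and the
// sparse symmetric K-inverse (CSC slots of a general sparse matrix).
// [[Rcpp::export(name = ".gibbs_het_residual")]]
List gibbs_het_residual(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                        NumericVector y, IntegerVector rec_group,
                        int n_groups, int n_fixed,
                        IntegerVector term_start, IntegerVector term_q,
                        List Kinv_list,
                        NumericVector var_init, NumericVector res_var_init,
                        int n_rounds, int burnin, int thin) {
  int n_eq = Wp.size() - 1;
  int n_rec = y.size();
  int n_terms = term_start.size();

  std::vector<const int*> Kp(n_terms), Ki(n_terms);
  std::vector<const double*> Kx(n_terms);
  std::vector<IntegerVector> Kp_keep(n_terms), Ki_keep(n_terms);
  std::vector<NumericVector> Kx_keep(n_terms);
  for (int t = 0; t < n_terms; ++t) {
    List K = Kinv_list[t];
    Kp_keep[t] = K["p"]; Ki_keep[t] = K["i"]; Kx_keep[t] = K["x"];
    Kp[t] = &Kp_keep[t][0]; Ki[t] = &Ki_keep[t][0]; Kx[t] = &Kx_keep[t][0];
  }
  // which term (or -1 for fixed) each equation belongs to
  std::vector<int> eq_term(n_eq, -1);
  for (int t = 0; t < n_terms; ++t)
    for (int k = 0; k < term_q[t]; ++k) eq_term[term_start[t] + k] = t;

  std::vector<double> theta(n_eq, 0.0);
  std::vector<double> e(y.begin(), y.end()); // residual y - W theta
  std::vector<double> sig(var_init.begin(), var_init.end());
  std::vector<double> sig_e(res_var_init.begin(), res_var_init.end());
  std::vector<int> ng(n_groups, 0);
  for (int i = 0; i < n_rec; ++i) ng[rec_group[i]]++;

  int n_keep = 0;
  for (int r = burnin; r < n_rounds; ++r) if ((r - burnin) % thin == 0) n_keep++;
  NumericMatrix res_chain(n_keep, n_groups);
  NumericMatrix var_chain(n_keep, n_terms);
  int keep_row = 0;

  RNGScope scope;
  for (int round = 0; round < n_rounds; ++round) {
    // --- location parameters ---
    for (int k = 0; k < n_eq; ++k) {
      double lhs = 0.0, rhs = 0.0;
      double old = theta[k];
      for (int q = Wp[k]; q < Wp[k + 1]; ++q) {
        int i = Wi[q];
        double prec = 1.0 / sig_e[rec_group[i]];
        double w = Wx[q];
        lhs += w * w * prec;
        rhs += w * prec * (e[i] + w * old);
      }
      int t = eq_term[k];
      if (t >= 0) {
        int loc = k - term_start[t];
        double st = sig[t];
        for (int q = Kp[t][loc]; q < Kp[t][loc + 1]; ++q) {
          int r2 = Ki[t][q];
          double v = Kx[t][q] / st;
          if (r2 == loc) lhs += v;
          else rhs -= v * theta[term_start[t] + r2];
        }
      }
      if (lhs <= 0.0) continue;
      double mean = rhs / lhs;
      double draw = mean + ::norm_rand() / std::sqrt(lhs);
      if (!std::isfinite(draw)) stop("Gibbs chain diverged: non-finite location draw");
      theta[k] = draw;
      double diff = draw - old;
      if (diff != 0.0)
        for (int q = Wp[k]; q < Wp[k + 1]; ++q) e[Wi[q]] -= Wx[q] * diff;
    }
    // --- random-term variances: sig ~ u'Kinv u / chisq(q - 2) ---
    for (int t = 0; t < n_terms; ++t) {
      double ss = 0.0;
      for (int c = 0; c < term_q[t]; ++c) {
        double acc = 0.0;
        for (int q = Kp[t][c]; q < Kp[t][c + 1]; ++q)
          acc += Kx[t][q] * theta[term_start[t] + Ki[t][q]];
        ss += acc * theta[term_start[t] + c];
      }
      double df = term_q[t] - 2.0;
      if (df < 1.0) df = 1.0;
      double draw = ss / ::Rf_rchisq(df);
      if (!std::isfinite(draw) || draw <= 0.0)
        stop("Gibbs chain diverged: non-finite variance draw");
      sig[t] = draw;
    }
    // --- group residual variances ---
    std::vector<double> ssg(n_groups, 0.0);
    for (int i = 0; i < n_rec; ++i) ssg[rec_group[i]] += e[i] * e[i];
    for (int g = 0; g < n_groups; ++g) {
      double df = ng[g] - 2.0;
      if (df < 1.0) df = 1.0;
      double draw = ssg[g] / ::Rf_rchisq(df);
      if (!std::isfinite(draw) || draw <= 0.0)
        stop("Gibbs chain diverged: non-finite residual draw");
      sig_e[g] = draw;
    }
    if (round >= burnin && (round - burnin) % thin == 0) {
      for (int g = 0; g < n_groups; ++g) res_chain(keep_row, g) = sig_e[g];
      for (int t = 0; t < n_terms; ++t) var_chain(keep_row, t) = sig[t];
      keep_row++;
    }
  }
  return List::create(_["residual_chain"] = res_chain,
                      _["variance_chain"] = var_chain,
                      _["theta"] = NumericVector(theta.begin(), theta.end()));
}
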