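#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Gaussian sire-dam variance component model
//   y_ijk = mu + s_i + d_j + e_ijk
// with independent normal random effects and scaled-inverse-chi-square
// (inverse-gamma family) priors on each variance, parameterized by a
// prior degree-of-belief nu and prior scale V. The flat prior on mu is
// improper but the conditional is proper for n >= 1.
//
// Draws use R's RNG so set.seed() on the R side makes chains exactly
// reproducible.

static double rinvchisq(double df, double scale_ss) {
  // scale_ss = nu0*V0 + SS ; returns scale_ss / chisq(df)
  double x = R::rchisq(df);
  if (x <= 0) x = 1e-300;
  return scale_ss / x;
}

// [[Rcpp::export]]
NumericMatrix gibbs_sire_dam(NumericVector y, IntegerVector sire,
                             IntegerVector dam, int n_sire, int n_dam,
                             int n_iter, int burn_in, int thin,
                             double nu, double V) {
  int n = y.size();
  std::vector<double> s(n_sire, 0.0), d(n_dam, 0.0);
  std::vector<int> ns(n_sire, 0), nd(n_dam, 0);
  for (int k = 0; k < n; ++k) { ns[sire[k]]++; nd[dam[k]]++; }

  double ybar = mean(y);
  double mu = ybar, Vs = 0.1, Vd = 0.1, Ve = 1.0;
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, 4);
  colnames(out) = CharacterVector::create("V_sire", "V_dam", "V_resid", "mu");

  std::vector<double> rs(n_sire), rd(n_dam);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // mu | rest
    double acc = 0.0;
    for (int k = 0; k < n; ++k) acc += y[k] - s[sire[k]] - d[dam[k]];
    mu = R::rnorm(acc / n, std::sqrt(Ve / n));

    // sire effects
    std::fill(rs.begin(), rs.end(), 0.0);
    for (int k = 0; k < n; ++k) rs[sire[k]] += y[k] - mu - d[dam[k]];
    for (int i = 0; i < n_sire; ++i) {
      double prec = ns[i] / Ve + 1.0 / Vs;
      s[i] = R::rnorm((rs[i] / Ve) / prec, std::sqrt(1.0 / prec));
    }

    // dam effects
    std::fill(rd.begin(), rd.end(), 0.0);
    for (int k = 0; k < n; ++k) rd[dam[k]] += y[k] - mu - s[sire[k]];
    for (int j = 0; j < n_dam; ++j) {
      double prec = nd[j] / Ve + 1.0 / Vd;
      d[j] = R::rnorm((rd[j] / Ve) / prec, std::sqrt(1.0 / prec));
    }

    // variance components
    double ss_s = 0.0, ss_d = 0.0, ss_e = 0.0;
    for (int i = 0; i < n_sire; ++i) ss_s += s[i] * s[i];
    for (int j = 0; j < n_dam; ++j) ss_d += d[j] * d[j];
    for (int k = 0; k < n; ++k) {
      double e = y[k] - mu - s[sire[k]] - d[dam[k]];
      ss_e += e * e;
    }
    Vs = rinvchisq(nu + n_sire, nu * V + ss_s);
    Vd = rinvchisq(nu + n_dam, nu * V + ss_d);
    Ve = rinvchisq(nu + n, nu * V + ss_e);

    if (it >= burn_in && ((it - burn_in) % thin) == 0 && kept < n_keep) {
      out(kept, 0) = Vs;
      out(kept, 1) = Vd;
      out(kept, 2) = Ve;
      out(kept, 3) = mu;
      ++kept;
    }
  }
  return out;
}
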