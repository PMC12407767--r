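#include <Rcpp.h>
using namespace Rcpp;

// Per-droplet, per-hypothesis fitting kernel.
//
// For every flagged (droplet, hypothesis) pair and each modality, maximize
// over the ambient fraction alpha the penalized log-likelihood
//   f(alpha) = sum_m log[(1 - alpha) d_m + alpha a_m]
//            + kappa * (beta log(alpha) + (1 - beta) log(1 - alpha))
// where a_m and d_m are the molecule's ambient and donor-mix likelihoods
// on a per-molecule scaled natural scale (exp of the source log-likelihood
// minus its row max; the scaling constant is alpha-free and restored by
// the caller). f is strictly concave on (0, 1) for kappa > 0, so a
// safeguarded Newton iteration (bisection fallback on the sign of f')
// converges to the unique maximum. The empty hypothesis (h = 0) has alpha
// fixed at 1 and needs no optimization.
//
// alpha_* and molsum_* (the molecule-sum part of the log-likelihood at
// the fitted alpha, excluding scaling constants) are updated in place.

static inline double donor_lik(const double* E, int r, int nmol,
                               int h, int i, int j) {
  if (h == 1) return E[(size_t)i * nmol + r];
  return 0.5 * (E[(size_t)i * nmol + r] + E[(size_t)j * nmol + r]);
}

// [[Rcpp::export(name = ".fit_droplets_kernel")]]
void fit_droplets_kernel(NumericMatrix E, IntegerMatrix bounds,
                         IntegerVector hyp_h, IntegerVector hyp_i,
                         IntegerVector hyp_j, LogicalMatrix active,
                         NumericMatrix alpha_rna, NumericMatrix alpha_atac,
                         NumericMatrix molsum_rna, NumericMatrix molsum_atac,
                         double kappa, NumericVector beta,
                         double alpha_tol, int max_newton) {
  const int nD = bounds.nrow();
  const int nH = hyp_h.size();
  const int nmol = E.nrow();
  const int amb = E.ncol() - 1;
  const double* Ep = REAL(E);
  const double tiny = 1e-300;
  std::vector<double> buf_d, buf_r;

  for (int d = 0; d < nD; ++d) {
    for (int k = 0; k < nH; ++k) {
      if (!active(d, k)) continue;
      const int h = hyp_h[k];
      const int di = hyp_i[k];
      const int dj = hyp_j[k];
      for (int mod = 0; mod < 2; ++mod) {
        // shallow copies share the underlying SEXP: writes go through
        NumericMatrix am = (mod == 0) ? alpha_rna : alpha_atac;
        NumericMatrix ms = (mod == 0) ? molsum_rna : molsum_atac;
        const int s = bounds(d, 2 * mod);
        const int e = bounds(d, 2 * mod + 1);
        if (h == 0) {
          am(d, k) = 1.0;
          double tot = 0.0;
          for (int r = s; r < e; ++r) {
            double a = Ep[(size_t)amb * nmol + r];
            tot += std::log(a > tiny ? a : tiny);
          }
          ms(d, k) = tot;
          continue;
        }
        if (s >= e) {  // no informative molecules in this modality
          am(d, k) = beta[mod];
          ms(d, k) = 0.0;
          continue;
        }
        // buffer the molecule likelihoods once; Newton iterations only
        // touch the buffers
        const int n = e - s;
        buf_d.resize(n);
        buf_r.resize(n);
        for (int r = s; r < e; ++r) {
          double a = Ep[(size_t)amb * nmol + r];
          double dd = donor_lik(Ep, r, nmol, h, di, dj);
          buf_d[r - s] = dd;
          buf_r[r - s] = a - dd;
        }
        double alpha = am(d, k);
        if (!(alpha > 1e-6)) alpha = 1e-6;
        if (!(alpha < 1.0 - 1e-6)) alpha = 1.0 - 1e-6;
        double lo = 1e-9, hi = 1.0 - 1e-9;
        const double kb = kappa * beta[mod];
        const double kb1 = kappa * (1.0 - beta[mod]);
        for (int it = 0; it < max_newton; ++it) {
          double g1 = kb / alpha - kb1 / (1.0 - alpha);
          double g2 = -kb / (alpha * alpha)
                      - kb1 / ((1.0 - alpha) * (1.0 - alpha));
          for (int q = 0; q < n; ++q) {
            double t = buf_d[q] + alpha * buf_r[q];
            if (t < tiny) t = tiny;
            double rr = buf_r[q] / t;
            g1 += rr;
            g2 -= rr * rr;
          }
          if (g1 > 0.0) lo = alpha; else hi = alpha;
          double step = alpha - g1 / g2;
          if (!(step > lo && step < hi) || !R_finite(step))
            step = 0.5 * (lo + hi);
          double delta = std::abs(step - alpha);
          alpha = step;
          if (delta < alpha_tol) break;
        }
        double tot = 0.0;
        for (int q = 0; q < n; ++q) {
          double t = buf_d[q] + alpha * buf_r[q];
          if (t < tiny) t = tiny;
          tot += std::log(t);
        }
        am(d, k) = alpha;
        ms(d, k) = tot;
      }
    }
  }
}
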