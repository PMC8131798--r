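// Gibbs sampler for the sex-specific animal model.
//
// Model per record r of individual i with sex s:
//   y_r = mu_s + a[i,s] + ce[fam(i),s] + pe[i] + c[contest(r)] + e_r
// a-pairs (a_f, a_m) have prior N(0, G (x) A); only the own-sex component is
// observed. CE/PE/residual are sex-diagonal; contest variance is pooled.
// Conjugate updates throughout: Gaussian effects, inverse-Wishart G,
// scaled-inverse-chi-square diagonal variances. Uses R's RNG, so runs are
// reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0);
  if (g < 1e-300) g = 1e-300; // guard against underflow for tiny shapes
  return rate / g;
}

// Inverse-Wishart(Psi, df) via Bartlett on W ~ Wishart(df, Psi^{-1}), G = W^{-1}.
static void riwish2(const double Psi[3], double df, double G[3]) {
  // Psi, G stored as {xx, xy, yy}
  double det = Psi[0] * Psi[2] - Psi[1] * Psi[1];
  if (det < 1e-300) det = 1e-300;
  double S0 = Psi[2] / det, S1 = -Psi[1] / det, S2 = Psi[0] / det; // Psi^{-1}
  // chol lower of Psi^{-1}
  double l11 = std::sqrt(S0);
  double l21 = S1 / l11;
  double l22 = std::sqrt(std::max(S2 - l21 * l21, 1e-300));
  // Bartlett factor
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = R::norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  // T = L * A (lower): W = T T'
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  double W0 = t11 * t11;
  double W1 = t11 * t21;
  double W2 = t21 * t21 + t22 * t22;
  double dW = W0 * W2 - W1 * W1;
  if (dW < 1e-300) dW = 1e-300;
  G[0] = W2 / dW; G[1] = -W1 / dW; G[2] = W0 / dW;
}

// [[Rcpp::export(name = ".gibbs_animal")]]
List gibbs_animal(NumericVector y, IntegerVector sex_rec, IntegerVector ind,
                  IntegerVector ce_level, IntegerVector contest,
                  int n_ind, IntegerVector sex_ind,
                  IntegerVector ainv_p, IntegerVector ainv_j, NumericVector ainv_x,
                  int n_ce, IntegerVector ce_sex, int n_contest,
                  bool has_animal, bool has_ce, bool has_pe, bool has_contest,
                  bool px_animal, List prior, int niter, int burnin, int thin) {
  int nrec = y.size();
  // priors
  NumericVector G_V = prior["G_V"]; // length 3: xx, xy, yy
  double G_nu = prior["G_nu"];
  double ce_V = prior["ce_V"], ce_nu = prior["ce_nu"];
  double pe_V = prior["pe_V"], pe_nu = prior["pe_nu"];
  double c_V = prior["c_V"], c_nu = prior["c_nu"];
  NumericVector r_V = prior["r_V"]; // per sex
  double r_nu = prior["r_nu"];
  double fixed_var = prior["fixed_var"];
  // parameter expansion (animal block): G = diag(alpha) Psi diag(alpha)
  NumericVector psi_V = prior["psi_V"]; // length 3
  double psi_nu = prior["psi_nu"];
  NumericVector alpha_var = prior["alpha_var"]; // per sex

  // record lists
  std::vector<std::vector<int> > rec_sex(2), rec_ind(n_ind),
      rec_ce(std::max(n_ce, 1)), rec_contest(std::max(n_contest, 1));
  for (int r = 0; r < nrec; r++) {
    rec_sex[sex_rec[r]].push_back(r);
    rec_ind[ind[r]].push_back(r);
    if (has_ce && ce_level[r] >= 0) rec_ce[ce_level[r]].push_back(r);
    if (has_contest && contest[r] >= 0) rec_contest[contest[r]].push_back(r);
  }
  // pe levels: individuals with at least one record
  std::vector<int> n_pe_sex(2, 0);
  for (int i = 0; i < n_ind; i++)
    if (!rec_ind[i].empty()) n_pe_sex[sex_ind[i]]++;
  std::vector<int> n_ce_sex(2, 0);
  for (int l = 0; l < n_ce; l++) n_ce_sex[ce_sex[l]]++;

  // state
  double mu[2] = {0.0, 0.0};
  int n_s[2] = {(int)rec_sex[0].size(), (int)rec_sex[1].size()};
  for (int s = 0; s < 2; s++) {
    if (n_s[s] > 0) {
      double m = 0;
      for (size_t k = 0; k < rec_sex[s].size(); k++) m += y[rec_sex[s][k]];
      mu[s] = m / n_s[s];
    }
  }
  std::vector<double> a(2 * n_ind, 0.0); // a[2*i + s] (eta under PX)
  std::vector<double> ce(std::max(n_ce, 1), 0.0), pe(n_ind, 0.0),
      cc(std::max(n_contest, 1), 0.0);
  double G[3] = {G_V[0], G_V[1], G_V[2]}; // Psi under PX
  double alpha[2] = {1.0, 1.0};
  if (px_animal) {
    G[0] = psi_V[0]; G[1] = psi_V[1]; G[2] = psi_V[2];
    alpha[0] = std::sqrt(std::max(G_V[0], 1e-8));
    alpha[1] = std::sqrt(std::max(G_V[2], 1e-8));
  }
  if (!has_animal) { G[0] = G[2] = 1.0; G[1] = 0.0; }
  double v_ce[2] = {std::max(ce_V, 1e-12), std::max(ce_V, 1e-12)};
  double v_pe[2] = {std::max(pe_V, 1e-12), std::max(pe_V, 1e-12)};
  double v_c = std::max(c_V, 1e-12);
  double v_r[2] = {std::max(r_V[0], 1e-12), std::max(r_V[1], 1e-12)};

  std::vector<double> e(nrec);
  for (int r = 0; r < nrec; r++) e[r] = y[r] - mu[sex_rec[r]];

  int nkeep = (niter - burnin) / thin;
  NumericMatrix draws(nkeep, 12);
  std::vector<double> a_sum(2 * n_ind, 0.0), ce_sum(std::max(n_ce, 1), 0.0),
      pe_sum(n_ind, 0.0), cc_sum(std::max(n_contest, 1), 0.0),
      fit_sum(nrec, 0.0);
  int kept = 0;

  for (int it = 0; it < niter; it++) {
    // --- fixed effects (per-sex means) ---
    for (int s = 0; s < 2; s++) {
      double sum_e = 0;
      for (size_t k = 0; k < rec_sex[s].size(); k++) {
        e[rec_sex[s][k]] += mu[s];
        sum_e += e[rec_sex[s][k]];
      }
      double prec = n_s[s] / v_r[s] + 1.0 / fixed_var;
      double mean = (sum_e / v_r[s]) / prec;
      mu[s] = mean + R::norm_rand() / std::sqrt(prec);
      for (size_t k = 0; k < rec_sex[s].size(); k++) e[rec_sex[s][k]] -= mu[s];
    }

    if (has_animal) {
      // --- breeding-value pairs, single-site scan ---
      double detG = G[0] * G[2] - G[1] * G[1];
      if (detG < 1e-300) detG = 1e-300;
      double Gi0 = G[2] / detG, Gi1 = -G[1] / detG, Gi2 = G[0] / detG;
      for (int i = 0; i < n_ind; i++) {
        int s = sex_ind[i];
        double cs = alpha[s];
        double sum_e = 0;
        int ni = rec_ind[i].size();
        for (int k = 0; k < ni; k++) {
          e[rec_ind[i][k]] += cs * a[2 * i + s];
          sum_e += e[rec_ind[i][k]];
        }
        double dii = 0, u0 = 0, u1 = 0;
        for (int k = ainv_p[i]; k < ainv_p[i + 1]; k++) {
          int j = ainv_j[k];
          if (j == i) dii = ainv_x[k];
          else { u0 += ainv_x[k] * a[2 * j]; u1 += ainv_x[k] * a[2 * j + 1]; }
        }
        double P0 = dii * Gi0, P1 = dii * Gi1, P2 = dii * Gi2;
        double h0 = -(Gi0 * u0 + Gi1 * u1);
        double h1 = -(Gi1 * u0 + Gi2 * u1);
        if (s == 0) { P0 += cs * cs * ni / v_r[0]; h0 += cs * sum_e / v_r[0]; }
        else { P2 += cs * cs * ni / v_r[1]; h1 += cs * sum_e / v_r[1]; }
        double detP = P0 * P2 - P1 * P1;
        if (detP < 1e-300) detP = 1e-300;
        // Sigma = P^{-1}
        double S0 = P2 / detP, S1 = -P1 / detP, S2 = P0 / detP;
        double m0 = S0 * h0 + S1 * h1;
        double m1 = S1 * h0 + S2 * h1;
        double l11 = std::sqrt(S0);
        double l21 = S1 / l11;
        double l22 = std::sqrt(std::max(S2 - l21 * l21, 0.0));
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        a[2 * i] = m0 + l11 * z1;
        a[2 * i + 1] = m1 + l21 * z1 + l22 * z2;
        for (int k = 0; k < ni; k++) e[rec_ind[i][k]] -= cs * a[2 * i + s];
      }
      if (px_animal) {
        // working scale parameters alpha_s | eta: Gaussian regression update
        for (int s = 0; s < 2; s++) {
          double sxx = 0, sxy = 0;
          for (size_t k = 0; k < rec_sex[s].size(); k++) {
            int r = rec_sex[s][k];
            double x = a[2 * ind[r] + s];
            e[r] += alpha[s] * x;
            sxx += x * x;
            sxy += x * e[r];
          }
          double prec = sxx / v_r[s] + 1.0 / alpha_var[s];
          double mean = (sxy / v_r[s]) / prec;
          alpha[s] = mean + R::norm_rand() / std::sqrt(prec);
          for (size_t k = 0; k < rec_sex[s].size(); k++) {
            int r = rec_sex[s][k];
            e[r] -= alpha[s] * a[2 * ind[r] + s];
          }
        }
      }
      // --- G | a : inverse-Wishart ---
      double S[3] = {0, 0, 0};
      for (int i = 0; i < n_ind; i++) {
        for (int k = ainv_p[i]; k < ainv_p[i + 1]; k++) {
          int j = ainv_j[k];
          double v = ainv_x[k];
          S[0] += v * a[2 * i] * a[2 * j];
          S[1] += v * a[2 * i] * a[2 * j + 1];
          S[2] += v * a[2 * i + 1] * a[2 * j + 1];
        }
      }
      if (px_animal) {
        double Psi[3] = {psi_nu * psi_V[0] + S[0], psi_nu * psi_V[1] + S[1],
                         psi_nu * psi_V[2] + S[2]};
        riwish2(Psi, psi_nu + n_ind, G);
      } else {
        double Psi[3] = {G_nu * G_V[0] + S[0], G_nu * G_V[1] + S[1],
                         G_nu * G_V[2] + S[2]};
        riwish2(Psi, G_nu + n_ind, G);
      }
    }

    if (has_ce) {
      for (int l = 0; l < n_ce; l++) {
        int s = ce_sex[l];
        double sum_e = 0;
        int nl = rec_ce[l].size();
        for (int k = 0; k < nl; k++) {
          e[rec_ce[l][k]] += ce[l];
          sum_e += e[rec_ce[l][k]];
        }
        double prec = nl / v_r[s] + 1.0 / v_ce[s];
        double mean = (sum_e / v_r[s]) / prec;
        ce[l] = mean + R::norm_rand() / std::sqrt(prec);
        for (int k = 0; k < nl; k++) e[rec_ce[l][k]] -= ce[l];
      }
      for (int s = 0; s < 2; s++) {
        double ss = 0;
        for (int l = 0; l < n_ce; l++) if (ce_sex[l] == s) ss += ce[l] * ce[l];
        v_ce[s] = rinvgamma((ce_nu + n_ce_sex[s]) / 2.0,
                            (ce_nu * ce_V + ss) / 2.0);
      }
    }

    if (has_pe) {
      for (int i = 0; i < n_ind; i++) {
        int ni = rec_ind[i].size();
        if (ni == 0) continue;
        int s = sex_ind[i];
        double sum_e = 0;
        for (int k = 0; k < ni; k++) {
          e[rec_ind[i][k]] += pe[i];
          sum_e += e[rec_ind[i][k]];
        }
        double prec = ni / v_r[s] + 1.0 / v_pe[s];
        double mean = (sum_e / v_r[s]) / prec;
        pe[i] = mean + R::norm_rand() / std::sqrt(prec);
        for (int k = 0; k < ni; k++) e[rec_ind[i][k]] -= pe[i];
      }
      for (int s = 0; s < 2; s++) {
        double ss = 0;
        for (int i = 0; i < n_ind; i++)
          if (sex_ind[i] == s && !rec_ind[i].empty()) ss += pe[i] * pe[i];
        v_pe[s] = rinvgamma((pe_nu + n_pe_sex[s]) / 2.0,
                            (pe_nu * pe_V + ss) / 2.0);
      }
    }

    if (has_contest) {
      for (int l = 0; l < n_contest; l++) {
        int nl = rec_contest[l].size();
        if (nl == 0) continue;
        int s = sex_rec[rec_contest[l][0]];
        double sum_e = 0;
        for (int k = 0; k < nl; k++) {
          e[rec_contest[l][k]] += cc[l];
          sum_e += e[rec_contest[l][k]];
        }
        double prec = nl / v_r[s] + 1.0 / v_c;
        double mean = (sum_e / v_r[s]) / prec;
        cc[l] = mean + R::norm_rand() / std::sqrt(prec);
        for (int k = 0; k < nl; k++) e[rec_contest[l][k]] -= cc[l];
      }
      double ss = 0;
      for (int l = 0; l < n_contest; l++) ss += cc[l] * cc[l];
      v_c = rinvgamma((c_nu + n_contest) / 2.0, (c_nu * c_V + ss) / 2.0);
    }

    // --- residual variances ---
    for (int s = 0; s < 2; s++) {
      double ss = 0;
      for (size_t k = 0; k < rec_sex[s].size(); k++) {
        double er = e[rec_sex[s][k]];
        ss += er * er;
      }
      v_r[s] = rinvgamma((r_nu + n_s[s]) / 2.0, (r_nu * r_V[s] + ss) / 2.0);
    }

    // --- retain ---
    if (it >= burnin && (it - burnin) % thin == 0 && kept < nkeep) {
      draws(kept, 0) = mu[0]; draws(kept, 1) = mu[1];
      if (px_animal) {
        draws(kept, 2) = alpha[0] * alpha[0] * G[0];
        draws(kept, 3) = alpha[1] * alpha[1] * G[2];
        draws(kept, 4) = alpha[0] * alpha[1] * G[1];
      } else {
        draws(kept, 2) = G[0]; draws(kept, 3) = G[2]; draws(kept, 4) = G[1];
      }
      draws(kept, 5) = v_ce[0]; draws(kept, 6) = v_ce[1];
      draws(kept, 7) = v_pe[0]; draws(kept, 8) = v_pe[1];
      draws(kept, 9) = v_r[0]; draws(kept, 10) = v_r[1];
      draws(kept, 11) = v_c;
      for (int i = 0; i < n_ind; i++) {
        a_sum[2 * i] += alpha[0] * a[2 * i];
        a_sum[2 * i + 1] += alpha[1] * a[2 * i + 1];
      }
      for (int l = 0; l < n_ce; l++) ce_sum[l] += ce[l];
      for (int i = 0; i < n_ind; i++) pe_sum[i] += pe[i];
      for (int l = 0; l < n_contest; l++) cc_sum[l] += cc[l];
      for (int r = 0; r < nrec; r++) fit_sum[r] += y[r] - e[r];
      kept++;
    }
  }

  NumericMatrix a_mean(n_ind, 2);
  NumericVector ce_mean(std::max(n_ce, 1)), pe_mean(n_ind),
      cc_mean(std::max(n_contest, 1)), fitted(nrec);
  double denom = kept > 0 ? (double)kept : 1.0;
  for (int i = 0; i < n_ind; i++) {
    a_mean(i, 0) = a_sum[2 * i] / denom;
    a_mean(i, 1) = a_sum[2 * i + 1] / denom;
    pe_mean[i] = pe_sum[i] / denom;
  }
  for (int l = 0; l < n_ce; l++) ce_mean[l] = ce_sum[l] / denom;
  for (int l = 0; l < n_contest; l++) cc_mean[l] = cc_sum[l] / denom;
  for (int r = 0; r < nrec; r++) fitted[r] = fit_sum[r] / denom;

  return List::create(_["draws"] = draws, _["n_retained"] = kept,
                      _["bv_mean"] = a_mean, _["ce_mean"] = ce_mean,
                      _["pe_mean"] = pe_mean, _["contest_mean"] = cc_mean,
                      _["fitted"] = fitted);
}
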