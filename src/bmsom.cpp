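// Marginalized multi-species occupancy model: joint log-posterior with
// analytic gradients (non-centered parameterization) and a No-U-Turn sampler
// with dual-averaging step-size and diagonal mass-matrix adaptation.
//
// Parameter vector layout (unconstrained):
//   [0] mu_a  [1] mu_c  [2] log_sigma_a  [3] log_sigma_c  [4] atanh_rho
//   [5 .. 5+S)        z_a
//   [5+S .. 5+2S)     z_c
//   for each random occupancy term m: mu_m, log_sigma_m, z_m (S)
//   for each fixed occupancy term:    b_m
//   for each detection term:          d_q
//   if augmented:                     logit_omega
//
// Natural scale: a_i = mu_a + sigma_a z_a_i,
//   c_i = mu_c + sigma_c (rho z_a_i + sqrt(1-rho^2) z_c_i),
//   beta_m_i = mu_m + sigma_m z_m_i.
//
// Memory layout (cache-friendly): cell-indexed arrays use j + J*i (site
// fastest within species); visit arrays use i + S*(j + J*k). When there are
// no detection covariates, per-cell detection counts replace the visit loop.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double log1pexp_c(double x) {
  return x > 35.0 ? x : std::log1p(std::exp(x));
}
static inline double lse2(double a, double b) {
  return a > b ? a + std::log1p(std::exp(b - a))
               : b + std::log1p(std::exp(a - b));
}
static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct ModelData {
  int S, J, K;
  std::vector<int> y;        // S*J*K, i + S*(j + J*k)
  std::vector<int> vis;      // S*J*K
  std::vector<int> keep;     // S*J, j + J*i
  std::vector<int> ndet;     // S*J, j + J*i: detections over unmasked visits
  std::vector<int> nvis;     // S*J, j + J*i: unmasked visit count
  int n_u;
  std::vector<std::vector<double>> u_vals; // S*J (j + J*i) or J (site vector)
  std::vector<int> u_is_matrix;
  std::vector<int> u_random;
  int n_w;
  std::vector<std::vector<double>> w_vals; // J*K, j + J*k
  bool augmented;
  std::vector<int> observed; // S
  double mean_loc, mean_scale, sd_scale;
  int npar;

  int idx_zu(int m) const { // start of random term m's block
    int base = 5 + 2 * S, r = 0;
    for (int t = 0; t < m; ++t) if (u_random[t]) ++r;
    return base + r * (2 + S);
  }
  int n_random() const {
    int r = 0;
    for (int t = 0; t < n_u; ++t) if (u_random[t]) ++r;
    return r;
  }
  int idx_fixed() const { return 5 + 2 * S + n_random() * (2 + S); }
  int n_fixed() const { return n_u - n_random(); }
  int idx_d() const { return idx_fixed() + n_fixed(); }
  int idx_omega() const { return idx_d() + n_w; }
};

static ModelData unpack_data(const List& data) {
  ModelData md;
  md.S = as<int>(data["S"]);
  md.J = as<int>(data["J"]);
  md.K = as<int>(data["K"]);
  md.y = as<std::vector<int>>(data["y"]);
  md.vis = as<std::vector<int>>(data["vis"]);
  md.keep = as<std::vector<int>>(data["keep"]);
  List uv = data["u_vals"];
  md.n_u = uv.size();
  for (int m = 0; m < md.n_u; ++m)
    md.u_vals.push_back(as<std::vector<double>>(uv[m]));
  md.u_is_matrix = as<std::vector<int>>(data["u_is_matrix"]);
  md.u_random = as<std::vector<int>>(data["u_random"]);
  List wv = data["w_vals"];
  md.n_w = wv.size();
  for (int q = 0; q < md.n_w; ++q)
    md.w_vals.push_back(as<std::vector<double>>(wv[q]));
  md.augmented = as<bool>(data["augmented"]);
  md.observed = as<std::vector<int>>(data["observed"]);
  md.mean_loc = as<double>(data["mean_loc"]);
  md.mean_scale = as<double>(data["mean_scale"]);
  md.sd_scale = as<double>(data["sd_scale"]);
  md.npar = md.idx_omega() + (md.augmented ? 1 : 0);
  // per-cell detection counts (used on the intercept-only detection path)
  md.ndet.assign(md.S * md.J, 0);
  md.nvis.assign(md.S * md.J, 0);
  for (int k = 0; k < md.K; ++k)
    for (int j = 0; j < md.J; ++j)
      for (int i = 0; i < md.S; ++i) {
        long idx = i + (long)md.S * (j + (long)md.J * k);
        if (md.vis[idx]) {
          ++md.nvis[j + md.J * i];
          if (md.y[idx]) ++md.ndet[j + md.J * i];
        }
      }
  return md;
}

// Evaluate log posterior and (optionally) gradient. Optionally export
// per-retained-cell marginalized log-likelihoods (cell order: species outer,
// site inner).
static double model_eval(const ModelData& md, const double* par,
                         double* grad, double* cell_ll_out) {
  const int S = md.S, J = md.J, K = md.K;
  const double mu_a = par[0], mu_c = par[1];
  const double sigma_a = std::exp(par[2]), sigma_c = std::exp(par[3]);
  const double rho = std::tanh(par[4]);
  const double rt = std::sqrt(1.0 - rho * rho);
  const bool want_grad = grad != nullptr;
  const bool det_fast = md.n_w == 0;

  std::vector<double> a(S), c(S);
  const double* z_a = par + 5;
  const double* z_c = par + 5 + S;
  for (int i = 0; i < S; ++i) {
    a[i] = mu_a + sigma_a * z_a[i];
    c[i] = mu_c + sigma_c * (rho * z_a[i] + rt * z_c[i]);
  }
  std::vector<std::vector<double>> coef(md.n_u);
  std::vector<int> upos(md.n_u);
  {
    int fixed_at = md.idx_fixed();
    for (int m = 0; m < md.n_u; ++m) {
      coef[m].resize(S);
      if (md.u_random[m]) {
        int off = md.idx_zu(m);
        upos[m] = off;
        double mu_m = par[off], s_m = std::exp(par[off + 1]);
        for (int i = 0; i < S; ++i) coef[m][i] = mu_m + s_m * par[off + 2 + i];
      } else {
        upos[m] = fixed_at;
        for (int i = 0; i < S; ++i) coef[m][i] = par[fixed_at];
        ++fixed_at;
      }
    }
  }
  const double* d = par + md.idx_d();
  double omega = md.augmented ? invlogit(par[md.idx_omega()]) : 1.0;

  std::vector<double> wsum;
  if (!det_fast) {
    wsum.assign(J * K, 0.0);
    for (int q = 0; q < md.n_w; ++q) {
      const std::vector<double>& w = md.w_vals[q];
      for (int jk = 0; jk < J * K; ++jk) wsum[jk] += d[q] * w[jk];
    }
  }

  if (want_grad) std::fill(grad, grad + md.npar, 0.0);
  std::vector<double> G_a(want_grad ? S : 0, 0.0);
  std::vector<double> G_c(want_grad ? S : 0, 0.0);
  std::vector<std::vector<double>> G_coef;
  if (want_grad) G_coef.assign(md.n_u, std::vector<double>(S, 0.0));
  std::vector<double> g_d(want_grad ? md.n_w : 0, 0.0);
  double g_logit_omega = 0.0;

  double lp = 0.0;
  long cell_counter = 0;
  std::vector<double> theta_k(K), gt_k(K);

  for (int i = 0; i < S; ++i) {
    double T_i = 0.0;
    double sp_Ga = 0.0, sp_Gc = 0.0;
    std::vector<double> sp_Gcoef, sp_gd;
    if (want_grad && md.augmented) {
      sp_Gcoef.assign(md.n_u, 0.0);
      sp_gd.assign(md.n_w, 0.0);
    }
    // intercept-only detection: one theta per species, with precomputed
    // powers (1-theta)^nv so all-zero cells need no per-visit work
    double th_i = 0, log_th_i = 0, log_1mth_i = 0;
    double pow1m[64];
    if (det_fast) {
      double t = c[i];
      double u = std::exp(-t);
      th_i = 1.0 / (1.0 + u);
      log_th_i = -log1pexp_c(-t);
      log_1mth_i = -t + log_th_i; // log(1-th) = -t - log1p(e^-t)
      double om = 1.0 - th_i;
      pow1m[0] = 1.0;
      for (int k = 1; k <= K && k < 64; ++k) pow1m[k] = pow1m[k - 1] * om;
    }
    const int* keep_i = md.keep.data() + (long)J * i;
    const int* ndet_i = md.ndet.data() + (long)J * i;
    const int* nvis_i = md.nvis.data() + (long)J * i;
    const double* uptr[16];
    double ucf[16];
    for (int m = 0; m < md.n_u && m < 16; ++m) {
      uptr[m] = md.u_is_matrix[m] ? md.u_vals[m].data() + (long)J * i
                                  : md.u_vals[m].data();
      ucf[m] = coef[m][i];
    }

    for (int j = 0; j < J; ++j) {
      if (!keep_i[j]) continue;
      double s = a[i];
      for (int m = 0; m < md.n_u; ++m) s += ucf[m] * uptr[m][j];
      double u = std::exp(-s);
      double psi = 1.0 / (1.0 + u);

      double cll, gs, pA = 1.0, gC = 0.0;
      bool anydet;
      int nv, nd;
      if (det_fast) {
        nv = nvis_i[j]; nd = ndet_i[j];
        anydet = nd > 0;
        if (nv == 0) {
          cll = 0.0; gs = 0.0; pA = 0.0;
        } else if (anydet) {
          double log_psi = s > 35.0 ? 0.0 : -std::log1p(u);
          cll = log_psi + nd * log_th_i + (nv - nd) * log_1mth_i;
          gs = 1.0 - psi;
          gC = nd - nv * th_i;
        } else {
          // marginal = (psi (1-th)^nv + 1-psi) = (p0v + u)/(1 + u)
          //          = 1 + (p0v - 1)/(1 + u); stable for u -> Inf
          double p0v = pow1m[nv];
          cll = std::log1p((p0v - 1.0) / (1.0 + u));
          pA = p0v / (p0v + u);
          gs = pA - psi;
          gC = -pA * nv * th_i;
        }
      } else {
        double log_psi = s > 35.0 ? 0.0 : -std::log1p(u);
        double log_1mpsi = -s + log_psi;
        double ld = 0.0;
        anydet = false;
        nv = 0;
        for (int k = 0; k < K; ++k) {
          long idx = i + (long)S * (j + (long)J * k);
          if (!md.vis[idx]) { theta_k[k] = -1.0; continue; }
          ++nv;
          double t = c[i] + wsum[j + J * k];
          double uu = std::exp(-t);
          double th = 1.0 / (1.0 + uu);
          theta_k[k] = th;
          double lth = t > 35.0 ? 0.0 : -std::log1p(uu);
          if (md.y[idx]) { anydet = true; ld += lth; }
          else ld += -t + lth;
        }
        if (nv == 0) {
          cll = 0.0; gs = 0.0; pA = 0.0;
        } else if (anydet) {
          cll = log_psi + ld;
          gs = 1.0 - psi;
        } else {
          double A = log_psi + ld;
          cll = lse2(A, log_1mpsi);
          pA = std::exp(A - cll);
          gs = pA - psi;
        }
      }
      T_i += cll;
      if (cell_ll_out) cell_ll_out[cell_counter] = cll;
      ++cell_counter;

      if (want_grad && nv > 0) {
        double acc_a, acc_c;
        if (md.augmented) { acc_a = sp_Ga; acc_c = sp_Gc; }
        if (det_fast) {
          if (md.augmented) { sp_Ga += gs; sp_Gc += gC; }
          else { G_a[i] += gs; G_c[i] += gC; }
          for (int m = 0; m < md.n_u; ++m) {
            double uval = md.u_is_matrix[m] ? md.u_vals[m][j + (long)J * i]
                                            : md.u_vals[m][j];
            if (md.augmented) sp_Gcoef[m] += gs * uval;
            else G_coef[m][i] += gs * uval;
          }
        } else {
          for (int k = 0; k < K; ++k) {
            long idx = i + (long)S * (j + (long)J * k);
            if (!md.vis[idx] || theta_k[k] < 0) { gt_k[k] = 0.0; continue; }
            if (anydet) gt_k[k] = (md.y[idx] ? 1.0 : 0.0) - theta_k[k];
            else gt_k[k] = -pA * theta_k[k];
          }
          if (md.augmented) {
            sp_Ga += gs;
            for (int m = 0; m < md.n_u; ++m) {
              double uval = md.u_is_matrix[m] ? md.u_vals[m][j + (long)J * i]
                                              : md.u_vals[m][j];
              sp_Gcoef[m] += gs * uval;
            }
            for (int k = 0; k < K; ++k) {
              if (gt_k[k] == 0.0) continue;
              sp_Gc += gt_k[k];
              for (int q = 0; q < md.n_w; ++q)
                sp_gd[q] += gt_k[k] * md.w_vals[q][j + J * k];
            }
          } else {
            G_a[i] += gs;
            for (int m = 0; m < md.n_u; ++m) {
              double uval = md.u_is_matrix[m] ? md.u_vals[m][j + (long)J * i]
                                              : md.u_vals[m][j];
              G_coef[m][i] += gs * uval;
            }
            for (int k = 0; k < K; ++k) {
              if (gt_k[k] == 0.0) continue;
              G_c[i] += gt_k[k];
              for (int q = 0; q < md.n_w; ++q)
                g_d[q] += gt_k[k] * md.w_vals[q][j + J * k];
            }
          }
        }
        (void)acc_a; (void)acc_c;
      }
    }

    if (md.augmented) {
      double w_i;
      if (md.observed[i]) {
        lp += std::log(omega) + T_i;
        w_i = 1.0;
        g_logit_omega += (1.0 - omega);
      } else {
        double L = lse2(std::log1p(-omega), std::log(omega) + T_i);
        lp += L;
        double q_i = std::exp(std::log(omega) + T_i - L);
        w_i = q_i;
        g_logit_omega += q_i * (1.0 - omega) - (1.0 - q_i) * omega;
      }
      if (want_grad) {
        G_a[i] += w_i * sp_Ga;
        G_c[i] += w_i * sp_Gc;
        for (int m = 0; m < md.n_u; ++m) G_coef[m][i] += w_i * sp_Gcoef[m];
        for (int q = 0; q < md.n_w; ++q) g_d[q] += w_i * sp_gd[q];
      }
    } else {
      lp += T_i;
    }
  }

  // ---- priors (with normalizing constants) ---------------------------------
  const double LOG2PI = 1.8378770664093454836;
  auto norm_lp = [&](double x, double loc, double scl) {
    double z = (x - loc) / scl;
    return -0.5 * LOG2PI - std::log(scl) - 0.5 * z * z;
  };
  lp += norm_lp(mu_a, md.mean_loc, md.mean_scale);
  lp += norm_lp(mu_c, md.mean_loc, md.mean_scale);
  lp += std::log(2.0) + norm_lp(sigma_a, 0.0, md.sd_scale) + par[2];
  lp += std::log(2.0) + norm_lp(sigma_c, 0.0, md.sd_scale) + par[3];
  lp += std::log(0.5) + std::log(1.0 - rho * rho);
  for (int i = 0; i < S; ++i) {
    lp += norm_lp(z_a[i], 0.0, 1.0);
    lp += norm_lp(z_c[i], 0.0, 1.0);
  }
  for (int m = 0; m < md.n_u; ++m) {
    if (md.u_random[m]) {
      int off = md.idx_zu(m);
      double s_m = std::exp(par[off + 1]);
      lp += norm_lp(par[off], md.mean_loc, md.mean_scale);
      lp += std::log(2.0) + norm_lp(s_m, 0.0, md.sd_scale) + par[off + 1];
      for (int i = 0; i < S; ++i) lp += norm_lp(par[off + 2 + i], 0.0, 1.0);
    } else {
      lp += norm_lp(par[upos[m]], md.mean_loc, md.mean_scale);
    }
  }
  for (int q = 0; q < md.n_w; ++q)
    lp += norm_lp(d[q], md.mean_loc, md.mean_scale);
  if (md.augmented) lp += std::log(omega) + std::log1p(-omega);

  if (want_grad) {
    double g_mu_a = 0, g_mu_c = 0, g_ls_a = 0, g_ls_c = 0, g_ar = 0;
    for (int i = 0; i < S; ++i) {
      g_mu_a += G_a[i];
      g_mu_c += G_c[i];
      g_ls_a += G_a[i] * z_a[i] * sigma_a;
      double cdev = rho * z_a[i] + rt * z_c[i];
      g_ls_c += G_c[i] * cdev * sigma_c;
      grad[5 + i] += G_a[i] * sigma_a + G_c[i] * sigma_c * rho - z_a[i];
      grad[5 + S + i] += G_c[i] * sigma_c * rt - z_c[i];
      g_ar += G_c[i] * sigma_c * (z_a[i] * (1.0 - rho * rho) - rho * rt * z_c[i]);
    }
    grad[0] = g_mu_a - (mu_a - md.mean_loc) / (md.mean_scale * md.mean_scale);
    grad[1] = g_mu_c - (mu_c - md.mean_loc) / (md.mean_scale * md.mean_scale);
    grad[2] = g_ls_a - sigma_a * sigma_a / (md.sd_scale * md.sd_scale) + 1.0;
    grad[3] = g_ls_c - sigma_c * sigma_c / (md.sd_scale * md.sd_scale) + 1.0;
    grad[4] = g_ar - 2.0 * rho;
    for (int m = 0; m < md.n_u; ++m) {
      if (md.u_random[m]) {
        int off = md.idx_zu(m);
        double s_m = std::exp(par[off + 1]);
        double gmu = 0, gls = 0;
        for (int i = 0; i < S; ++i) {
          gmu += G_coef[m][i];
          gls += G_coef[m][i] * par[off + 2 + i] * s_m;
          grad[off + 2 + i] = G_coef[m][i] * s_m - par[off + 2 + i];
        }
        grad[off] = gmu - (par[off] - md.mean_loc) / (md.mean_scale * md.mean_scale);
        grad[off + 1] = gls - s_m * s_m / (md.sd_scale * md.sd_scale) + 1.0;
      } else {
        double g = 0;
        for (int i = 0; i < S; ++i) g += G_coef[m][i];
        grad[upos[m]] = g - (par[upos[m]] - md.mean_loc) / (md.mean_scale * md.mean_scale);
      }
    }
    for (int q = 0; q < md.n_w; ++q)
      grad[md.idx_d() + q] = g_d[q] - (d[q] - md.mean_loc) / (md.mean_scale * md.mean_scale);
    if (md.augmented)
      grad[md.idx_omega()] = g_logit_omega + 1.0 - 2.0 * omega;
  }
  return lp;
}

// [[Rcpp::export(name = ".cpp_model_lp_grad")]]
List cpp_model_lp_grad(List data, NumericVector pars, bool want_grad = true,
                       bool want_pointwise = false) {
  ModelData md = unpack_data(data);
  if ((int)pars.size() != md.npar)
    stop("parameter vector has length %d, expected %d", pars.size(), md.npar);
  int ncell = 0;
  for (int ij = 0; ij < md.S * md.J; ++ij) if (md.keep[ij]) ++ncell;
  std::vector<double> grad(want_grad ? md.npar : 0);
  std::vector<double> cll(want_pointwise ? ncell : 0);
  double lp = model_eval(md, REAL(pars),
                         want_grad ? grad.data() : nullptr,
                         want_pointwise ? cll.data() : nullptr);
  List out = List::create(_["lp"] = lp);
  if (want_grad) out["grad"] = NumericVector(grad.begin(), grad.end());
  if (want_pointwise) out["cell_loglik"] = NumericVector(cll.begin(), cll.end());
  return out;
}

// [[Rcpp::export(name = ".cpp_n_params")]]
int cpp_n_params(List data) { return unpack_data(data).npar; }

// [[Rcpp::export(name = ".cpp_pointwise")]]
NumericMatrix cpp_pointwise(List data, NumericMatrix draws) {
  ModelData md = unpack_data(data);
  if (draws.ncol() != md.npar) stop("draws have wrong number of columns");
  int ncell = 0;
  for (int ij = 0; ij < md.S * md.J; ++ij) if (md.keep[ij]) ++ncell;
  NumericMatrix out(draws.nrow(), ncell);
  std::vector<double> par(md.npar), cll(ncell);
  for (int s = 0; s < draws.nrow(); ++s) {
    for (int p = 0; p < md.npar; ++p) par[p] = draws(s, p);
    model_eval(md, par.data(), nullptr, cll.data());
    for (int cc = 0; cc < ncell; ++cc) out(s, cc) = cll[cc];
  }
  return out;
}

// ---------------------------------------------------------------------------
// No-U-Turn sampler (slice variant) with dual averaging and diagonal mass
// adaptation. Divergence: log joint drops more than 1000 below the slice.
// ---------------------------------------------------------------------------

struct NutsWorkspace {
  const ModelData* md;
  std::vector<double> inv_mass;
  long n_grad = 0;
  double eval(const double* q, double* g) {
    ++n_grad;
    return model_eval(*md, q, g, nullptr);
  }
};

static void leapfrog(NutsWorkspace& ws, std::vector<double>& q,
                     std::vector<double>& p, std::vector<double>& g,
                     double eps, double& lp) {
  int n = q.size();
  for (int i = 0; i < n; ++i) p[i] += 0.5 * eps * g[i];
  for (int i = 0; i < n; ++i) q[i] += eps * ws.inv_mass[i] * p[i];
  lp = ws.eval(q.data(), g.data());
  for (int i = 0; i < n; ++i) p[i] += 0.5 * eps * g[i];
}

static double kinetic(const NutsWorkspace& ws, const std::vector<double>& p) {
  double k = 0;
  for (size_t i = 0; i < p.size(); ++i) k += p[i] * p[i] * ws.inv_mass[i];
  return 0.5 * k;
}

struct TreeState {
  std::vector<double> q, p, g;
  double lp;
};

struct BuildResult {
  TreeState minus, plus, prop;
  double n;
  bool ok;
  bool divergent;
  double alpha, n_alpha;
};

static bool no_uturn(const NutsWorkspace& ws, const TreeState& minus,
                     const TreeState& plus) {
  double dot_m = 0, dot_p = 0;
  for (size_t i = 0; i < minus.q.size(); ++i) {
    double dq = plus.q[i] - minus.q[i];
    dot_m += dq * ws.inv_mass[i] * minus.p[i];
    dot_p += dq * ws.inv_mass[i] * plus.p[i];
  }
  return dot_m >= 0 && dot_p >= 0;
}

static BuildResult build_tree(NutsWorkspace& ws, const TreeState& z,
                              double log_u, int dir, int depth, double eps,
                              double H0) {
  BuildResult r;
  if (depth == 0) {
    TreeState z1 = z;
    double lp;
    leapfrog(ws, z1.q, z1.p, z1.g, dir * eps, lp);
    z1.lp = lp;
    double joint = lp - kinetic(ws, z1.p);
    r.divergent = !std::isfinite(joint) || (log_u - 1000.0 > joint);
    r.n = (log_u <= joint) ? 1.0 : 0.0;
    r.ok = !r.divergent;
    r.minus = r.plus = r.prop = z1;
    double a = std::exp(joint - H0);
    r.alpha = std::isfinite(a) ? std::min(1.0, a) : 0.0;
    r.n_alpha = 1.0;
    return r;
  }
  BuildResult r1 = build_tree(ws, z, log_u, dir, depth - 1, eps, H0);
  if (!r1.ok) return r1;
  BuildResult r2 = build_tree(ws, dir == 1 ? r1.plus : r1.minus, log_u, dir,
                              depth - 1, eps, H0);
  BuildResult out;
  out.minus = dir == 1 ? r1.minus : r2.minus;
  out.plus = dir == 1 ? r2.plus : r1.plus;
  out.n = r1.n + r2.n;
  out.divergent = r1.divergent || r2.divergent;
  out.n_alpha = r1.n_alpha + r2.n_alpha;
  out.alpha = (r1.alpha * r1.n_alpha + r2.alpha * r2.n_alpha) /
              std::max(out.n_alpha, 1.0);
  out.prop = r1.prop;
  if (out.n > 0 && r2.ok && R::unif_rand() < r2.n / out.n) out.prop = r2.prop;
  out.ok = r2.ok && !out.divergent && no_uturn(ws, out.minus, out.plus);
  return out;
}

// [[Rcpp::export(name = ".cpp_nuts")]]
List cpp_nuts(List data, NumericVector init, int warmup, int iter,
              double target_accept = 0.9, int max_treedepth = 10,
              bool adapt_mass = true) {
  ModelData md = unpack_data(data);
  int n = md.npar;
  if ((int)init.size() != n) stop("init has wrong length");
  NutsWorkspace ws;
  ws.md = &md;
  ws.inv_mass.assign(n, 1.0);

  std::vector<double> q(init.begin(), init.end()), g(n);
  double lp = ws.eval(q.data(), g.data());
  if (!std::isfinite(lp)) stop("non-finite log-probability at the initial values");

  double eps = 0.1, mu_da = std::log(10.0 * eps), log_eps_bar = 0.0,
         H_bar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;

  int init_buf = std::min(75, warmup / 4);
  int term_buf = std::min(50, warmup / 4);
  int win_start = init_buf, win_size = 25;
  int win_end = std::min(win_start + win_size, warmup - term_buf);
  std::vector<double> wm(n, 0.0), wm2(n, 0.0);
  long wn = 0;

  int total = warmup + iter;
  NumericMatrix draws(iter, n);
  NumericVector energy(iter), accept_stat(iter);
  IntegerVector divergent(iter), treedepth(iter);
  int div_total = 0;

  for (int it = 0; it < total; ++it) {
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = R::norm_rand() / std::sqrt(ws.inv_mass[i]);
    double H0 = lp - kinetic(ws, p);
    double log_u = H0 - R::exp_rand();

    TreeState zpm; zpm.q = q; zpm.p = p; zpm.g = g; zpm.lp = lp;
    TreeState zminus = zpm, zplus = zpm, zprop = zpm;
    double n_acc = 1.0;
    bool ok = true, any_div = false;
    double alpha_sum = 0, n_alpha_sum = 0;
    int depth = 0;
    while (ok && depth < max_treedepth) {
      int dir = R::unif_rand() < 0.5 ? -1 : 1;
      BuildResult r = build_tree(ws, dir == 1 ? zplus : zminus, log_u, dir,
                                 depth, eps, H0);
      if (dir == 1) zplus = r.plus; else zminus = r.minus;
      any_div = any_div || r.divergent;
      alpha_sum += r.alpha * r.n_alpha;
      n_alpha_sum += r.n_alpha;
      if (r.ok && R::unif_rand() < r.n / std::max(n_acc, 1.0)) zprop = r.prop;
      n_acc += r.n;
      ok = r.ok && no_uturn(ws, zminus, zplus);
      ++depth;
    }
    q = zprop.q; g = zprop.g; lp = zprop.lp;
    double a_mean = n_alpha_sum > 0 ? alpha_sum / n_alpha_sum : 0.0;

    if (it < warmup) {
      double m = it + 1;
      H_bar = (1.0 - 1.0 / (m + t0)) * H_bar +
              (target_accept - a_mean) / (m + t0);
      double log_eps = mu_da - std::sqrt(m) / gamma_da * H_bar;
      double w = std::pow(m, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (adapt_mass && warmup >= 150 && it >= win_start && it < win_end) {
        ++wn;
        for (int i = 0; i < n; ++i) {
          double dlt = q[i] - wm[i];
          wm[i] += dlt / wn;
          wm2[i] += dlt * (q[i] - wm[i]);
        }
        if (it == win_end - 1 && wn > 4) {
          for (int i = 0; i < n; ++i) {
            double v = wm2[i] / (wn - 1);
            v = (wn / (wn + 5.0)) * v + 1e-3 * (5.0 / (wn + 5.0));
            ws.inv_mass[i] = std::max(v, 1e-8);
          }
          std::fill(wm.begin(), wm.end(), 0.0);
          std::fill(wm2.begin(), wm2.end(), 0.0);
          wn = 0;
          win_size *= 2;
          win_start = win_end;
          win_end = std::min(win_start + win_size, warmup - term_buf);
          if (warmup - term_buf - win_end < win_size) win_end = warmup - term_buf;
          mu_da = std::log(10.0) + std::log(eps);
          H_bar = 0.0; log_eps_bar = std::log(eps);
        }
      }
      if (it == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      int s = it - warmup;
      for (int i = 0; i < n; ++i) draws(s, i) = q[i];
      energy[s] = -(zprop.lp - kinetic(ws, zprop.p));
      divergent[s] = any_div ? 1 : 0;
      treedepth[s] = depth;
      accept_stat[s] = a_mean;
      if (any_div) ++div_total;
    }
  }

  return List::create(
    _["draws"] = draws, _["energy"] = energy, _["divergent"] = divergent,
    _["treedepth"] = treedepth, _["accept_stat"] = accept_stat,
    _["stepsize"] = eps, _["n_divergent"] = div_total,
    _["inv_mass"] = NumericVector(ws.inv_mass.begin(), ws.inv_mass.end()),
    _["n_grad_evals"] = (double)ws.n_grad);
}
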