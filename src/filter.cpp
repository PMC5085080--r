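#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Rao-Blackwellized particle filter session loop.
//
// Each particle carries a nominal position z (cm), a private heading
// estimate psi, and an association map (visit mass + weights from lattice
// nodes to the 228-cell boundary code). Grid phases are exact linear images
// of z (phase accumulators share every displacement increment with z), so z
// is carried as the sufficient statistic of the multi-module phase state;
// readout cell activity is evaluated from z through the module bank.
//
// RNG draw order per step (reproduced by the R reference implementation):
// for each particle p: e_head, e_x, e_y ~ N(0,1); then one uniform draw if
// resampling triggers this step.

static inline double wrap_pi(double a) {
  return a - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
}

static const int ND = 19, NTH = 12, NBC = 228;

// [[Rcpp::export]]
List sifm_filter_cpp(
    NumericVector dphi, NumericVector lam,            // S shared cues
    NumericMatrix obs_dist, IntegerMatrix obs_hit,    // Rr x S
    NumericVector obs_ang,                            // Rr egocentric angles
    NumericVector compass,                            // S (NA = unavailable)
    IntegerVector regime,                             // S: 0 vis, 1 dark, 2 st
    double dt,
    NumericVector scales, NumericMatrix axes,         // M, M x 3
    NumericVector bc_d, NumericVector bc_sigr,
    IntegerVector bc_short, NumericVector bc_th, double sig_th,
    double lx0, double ly0, int nx, int ny, double spacing,
    double sigma_g, double dmax,
    int n_particles, double comp_sd, double head_jit, double sigma_e,
    double ess_frac, bool resample_always, int resample_min_interval,
    bool learning_on, bool feedback_on, double compass_kappa,
    int learn_rule, double eta,
    NumericMatrix z0, NumericVector psi0, NumericVector w0,
    Nullable<NumericMatrix> map_W0, Nullable<NumericVector> map_mass0,
    IntegerVector rc_module, NumericMatrix rc_off,
    IntegerVector track_particles, int track_module,
    NumericVector track_off) {

  RNGScope scope;
  const int S = dphi.size();
  const int P = n_particles;
  const int M = scales.size();
  const int G = rc_module.size();
  const int Rr = obs_ang.size();
  const int N = nx * ny;
  const int hw = (int)std::ceil(dmax / spacing);
  const double inv2sg2 = 1.0 / (2.0 * sigma_g * sigma_g);
  const double inv2st2 = 1.0 / (2.0 * sig_th * sig_th);
  const double dmax2 = dmax * dmax;
  const double ang_supp = 3.5 * sig_th;

  // maps are per-particle during learning; during recall (learning off)
  // maps never change, so all particles share the single checkpoint map
  const bool shared_map = !learning_on;
  const int PM = shared_map ? 1 : P;

  // particle state
  std::vector<double> zx(P), zy(P), psi(P), w(P);
  for (int p = 0; p < P; ++p) {
    zx[p] = z0(p, 0); zy[p] = z0(p, 1); psi[p] = psi0[p]; w[p] = w0[p];
  }
  // maps: per-particle contiguous blocks
  std::vector<float> W((size_t)PM * N * NBC, 0.0f);
  std::vector<float> mass((size_t)PM * N, 0.0f);
  if (map_W0.isNotNull()) {
    NumericMatrix W0(map_W0);
    NumericVector m0(map_mass0);
    std::vector<float> Wrow((size_t)N * NBC);
    std::vector<float> mrow(N);
    for (int n = 0; n < N; ++n) {
      mrow[n] = (float)m0[n];
      for (int c = 0; c < NBC; ++c) Wrow[(size_t)n * NBC + c] = (float)W0(n, c);
    }
    for (int p = 0; p < PM; ++p) {
      std::memcpy(&W[(size_t)p * N * NBC], Wrow.data(),
                  sizeof(float) * N * NBC);
      std::memcpy(&mass[(size_t)p * N], mrow.data(), sizeof(float) * N);
    }
  }

  // admissible error cells per regime (dark: short-range rows only)
  std::vector<int> adm_all, adm_short;
  for (int j = 0; j < NTH; ++j)
    for (int i = 0; i < ND; ++i) {
      adm_all.push_back(j * ND + i);
      if (bc_short[i]) adm_short.push_back(j * ND + i);
    }

  // precomputed per-module wavenumbers and axis unit vectors
  std::vector<double> kmod(M);
  std::vector<double> ux(M * 3), uy(M * 3);
  for (int m = 0; m < M; ++m) {
    kmod[m] = 2.0 * M_PI / scales[m];
    for (int j = 0; j < 3; ++j) {
      ux[m * 3 + j] = std::cos(axes(m, j));
      uy[m * 3 + j] = std::sin(axes(m, j));
    }
  }

  // outputs
  NumericMatrix grid_rates(G, S), bc_rates(NBC, S), decoded(S, 2);
  NumericVector err_mean(S), ess_out(S), psi_mean(S);
  const int NT = track_particles.size();
  NumericMatrix track_rates(NT > 0 ? NT : 1, NT > 0 ? S : 1);
  int n_resample = 0, n_degenerate = 0, last_resample = -1000000;

  // scratch
  std::vector<float> sensed(NBC), pred(NBC);
  std::vector<float> preds((size_t)P * NBC);
  std::vector<double> radial((size_t)Rr * ND);
  std::vector<int> hit_idx(Rr);
  std::vector<double> errv(P);
  std::vector<float> exs(2 * hw + 1), eys(2 * hw + 1);
  std::vector<double> bc_acc(NBC);

  for (int s = 0; s < S; ++s) {
    const int reg = regime[s];
    const bool compass_ok = R_finite(compass[s]);
    // shared radial kernel factors for this step's hits
    int nh = 0;
    for (int r = 0; r < Rr; ++r) {
      if (obs_hit(r, s)) {
        double d = obs_dist(r, s);
        for (int i = 0; i < ND; ++i) {
          double u = (d - bc_d[i]) / bc_sigr[i];
          radial[(size_t)nh * ND + i] = std::exp(-0.5 * u * u);
        }
        hit_idx[nh++] = r;
      }
    }

    std::fill(bc_acc.begin(), bc_acc.end(), 0.0);
    double dec_x = 0, dec_y = 0, e_sum = 0, psc = 0, pss = 0;

    for (int p = 0; p < P; ++p) {
      double e_h = norm_rand(), e_x = norm_rand(), e_y = norm_rand();
      // heading: shared angular cue + private jitter, compass blending
      psi[p] += dphi[s] + e_h * head_jit * std::sqrt(dt);
      // position / grid phase advance with compensatory noise (one 2-D
      // jitter shared by all modules of this particle)
      double sn = comp_sd * std::sqrt(dt);
      zx[p] += lam[s] * std::cos(psi[p]) + e_x * sn;
      zy[p] += lam[s] * std::sin(psi[p]) + e_y * sn;

      // sensory boundary code via private heading
      std::fill(sensed.begin(), sensed.end(), 0.0f);
      for (int h = 0; h < nh; ++h) {
        int r = hit_idx[h];
        double alpha = obs_ang[r] + psi[p];
        const double* rad = &radial[(size_t)h * ND];
        for (int j = 0; j < NTH; ++j) {
          double delta = wrap_pi(alpha - bc_th[j]);
          if (std::fabs(delta) > ang_supp) continue;
          float A = (float)std::exp(-delta * delta * inv2st2);
          float* cell = &sensed[j * ND];
          for (int i = 0; i < ND; ++i) {
            float v = A * (float)rad[i];
            if (v > cell[i]) cell[i] = v;
          }
        }
      }
      if (reg == 1) // darkness: long-range boundary cells cannot be driven
        for (int j = 0; j < NTH; ++j)
          for (int i = 0; i < ND; ++i)
            if (!bc_short[i]) sensed[j * ND + i] = 0.0f;

      // association map update + predictive boundary code over the kernel
      // stencil around the particle's nominal position
      int cix = (int)std::floor((zx[p] - lx0) / spacing + 0.5);
      int ciy = (int)std::floor((zy[p] - ly0) / spacing + 0.5);
      int ix0 = cix - hw, ix1 = cix + hw, iy0 = ciy - hw, iy1 = ciy + hw;
      if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0;
      if (ix1 > nx - 1) ix1 = nx - 1; if (iy1 > ny - 1) iy1 = ny - 1;
      for (int ix = ix0; ix <= ix1; ++ix) {
        double dx = zx[p] - (lx0 + ix * spacing);
        exs[ix - ix0] = (float)std::exp(-dx * dx * inv2sg2);
      }
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = zy[p] - (ly0 + iy * spacing);
        eys[iy - iy0] = (float)std::exp(-dy * dy * inv2sg2);
      }
      std::fill(pred.begin(), pred.end(), 0.0f);
      double den = 0.0;
      const int pm = shared_map ? 0 : p;
      float* Wp = &W[(size_t)pm * N * NBC];
      float* mp = &mass[(size_t)pm * N];
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = zy[p] - (ly0 + iy * spacing);
        double dy2 = dy * dy;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = zx[p] - (lx0 + ix * spacing);
          if (dx * dx + dy2 > dmax2) continue;
          float k = exs[ix - ix0] * eys[iy - iy0];
          int n = iy * nx + ix;
          float* Wn = Wp + (size_t)n * NBC;
          if (learning_on) {
            mp[n] += k;
            // running average over visit mass, or prediction-error delta rule
            float lr = learn_rule == 0 ? k / mp[n] : (float)eta * k;
            if (lr > 1.0f) lr = 1.0f;
            for (int c = 0; c < NBC; ++c)
              Wn[c] += lr * (sensed[c] - Wn[c]);
          }
          float km = k * mp[n];
          if (km > 0) {
            den += km;
            for (int c = 0; c < NBC; ++c) pred[c] += km * Wn[c];
          }
        }
      }
      if (den > 0) {
        float inv = (float)(1.0 / den);
        for (int c = 0; c < NBC; ++c) pred[c] *= inv;
      }

      // boundary prediction error (RMS over regime-admissible cells)
      const std::vector<int>& adm = (reg == 1) ? adm_short : adm_all;
      double ss = 0;
      for (size_t a = 0; a < adm.size(); ++a) {
        double dv = (double)pred[adm[a]] - (double)sensed[adm[a]];
        ss += dv * dv;
      }
      errv[p] = std::sqrt(ss / adm.size());
      std::memcpy(&preds[(size_t)p * NBC], pred.data(), sizeof(float) * NBC);
    }

    // importance weights: boundary prediction error (Gaussian) and, when
    // available, the compass cue (von Mises on the private heading)
    if (feedback_on) {
      std::vector<double> lw(P);
      double lmax = -1e300;
      for (int p = 0; p < P; ++p) {
        lw[p] = -errv[p] * errv[p] / (2.0 * sigma_e * sigma_e);
        if (compass_ok)
          lw[p] += compass_kappa * std::cos(psi[p] - compass[s]);
        if (lw[p] > lmax) lmax = lw[p];
      }
      double sw = 0;
      for (int p = 0; p < P; ++p) {
        w[p] *= std::exp(lw[p] - lmax);
        sw += w[p];
      }
      if (sw <= 0 || !R_finite(sw)) {
        ++n_degenerate;
        for (int p = 0; p < P; ++p) w[p] = 1.0 / P;
      } else {
        for (int p = 0; p < P; ++p) w[p] /= sw;
      }
    }

    double ess = 0;
    for (int p = 0; p < P; ++p) ess += w[p] * w[p];
    ess = 1.0 / ess;
    ess_out[s] = ess;

    // step outputs (post-reweight weights)
    for (int p = 0; p < P; ++p) {
      dec_x += w[p] * zx[p]; dec_y += w[p] * zy[p];
      e_sum += w[p] * errv[p];
      psc += w[p] * std::cos(psi[p]); pss += w[p] * std::sin(psi[p]);
      const float* pp = &preds[(size_t)p * NBC];
      for (int c = 0; c < NBC; ++c) bc_acc[c] += w[p] * pp[c];
      for (int g = 0; g < G; ++g) {
        int m = rc_module[g] - 1;
        double f = 1.0;
        for (int j = 0; j < 3 && f > 0; ++j) {
          double ph = kmod[m] * (zx[p] * ux[m * 3 + j] + zy[p] * uy[m * 3 + j]) +
                      rc_off(g, j);
          double cv = std::cos(ph);
          f = cv > 0 ? f * cv : 0.0;
        }
        grid_rates(g, s) += w[p] * f;
      }
    }
    // per-particle tracked cells (phase-matched cells across grid codes)
    for (int ti = 0; ti < NT; ++ti) {
      int p = track_particles[ti] - 1;
      int m = track_module - 1;
      double f = 1.0;
      for (int j = 0; j < 3 && f > 0; ++j) {
        double ph = kmod[m] * (zx[p] * ux[m * 3 + j] + zy[p] * uy[m * 3 + j]) +
                    track_off[j];
        double cv = std::cos(ph);
        f = cv > 0 ? f * cv : 0.0;
      }
      track_rates(ti, s) = f;
    }
    decoded(s, 0) = dec_x; decoded(s, 1) = dec_y;
    err_mean[s] = e_sum;
    psi_mean[s] = std::atan2(pss, psc);
    for (int c = 0; c < NBC; ++c) bc_rates(c, s) = bc_acc[c];

    // resampling (with a refractory interval limiting map-copy churn)
    if (resample_always ||
        (ess < ess_frac * P &&
         (n_resample == 0 || s - last_resample >= resample_min_interval))) {
      ++n_resample;
      last_resample = s;
      double u = unif_rand() / P;
      std::vector<int> counts(P, 0);
      double cum = 0; int i = 0;
      for (int p = 0; p < P; ++p) {
        cum += w[p];
        while (i < P && u + (double)i / P < cum) { ++counts[p]; ++i; }
      }
      std::vector<int> dead;
      for (int p = 0; p < P; ++p) if (counts[p] == 0) dead.push_back(p);
      size_t di = 0;
      for (int p = 0; p < P; ++p) {
        for (int c = 1; c < counts[p]; ++c) {
          int q = dead[di++];
          zx[q] = zx[p]; zy[q] = zy[p]; psi[q] = psi[p];
          if (!shared_map) {
            std::memcpy(&W[(size_t)q * N * NBC], &W[(size_t)p * N * NBC],
                        sizeof(float) * N * NBC);
            std::memcpy(&mass[(size_t)q * N], &mass[(size_t)p * N],
                        sizeof(float) * N);
          }
        }
      }
      for (int p = 0; p < P; ++p) w[p] = 1.0 / P;
    }
  }

  // checkpoint map: highest-weight particle
  int best = 0;
  for (int p = 1; p < P; ++p) if (w[p] > w[best]) best = p;
  NumericMatrix map_W(N, NBC);
  NumericVector map_mass(N);
  {
    const int bm = shared_map ? 0 : best;
    float* Wp = &W[(size_t)bm * N * NBC];
    float* mp = &mass[(size_t)bm * N];
    for (int n = 0; n < N; ++n) {
      map_mass[n] = mp[n];
      for (int c = 0; c < NBC; ++c) map_W(n, c) = Wp[(size_t)n * NBC + c];
    }
  }
  NumericMatrix fin_z(P, 2);
  NumericVector fin_psi(P), fin_w(P);
  for (int p = 0; p < P; ++p) {
    fin_z(p, 0) = zx[p]; fin_z(p, 1) = zy[p];
    fin_psi[p] = psi[p]; fin_w[p] = w[p];
  }

  return List::create(
      _["grid_rates"] = grid_rates, _["bc_rates"] = bc_rates,
      _["err_mean"] = err_mean, _["ess"] = ess_out, _["decoded"] = decoded,
      _["psi_mean"] = psi_mean, _["n_resample"] = n_resample,
      _["n_degenerate"] = n_degenerate, _["track_rates"] = track_rates,
      _["map_W"] = map_W,
      _["map_mass"] = map_mass, _["best_particle"] = best + 1,
      _["z"] = fin_z, _["psi"] = fin_psi, _["w"] = fin_w);
}
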