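// Fast simulation kernel for the four-area recurrent E/I rate model.
//
// Exploits the exact structure of the connectome: every sub-block of the
// dense weight matrix is a uniform (all-to-all) part plus an aligned
// (one-to-one diagonal) part, so recurrent input reduces to block-level
// sums plus a handful of per-unit aligned terms.  The reduction is
// verified against the dense R reference implementation in the test
// suite.  All randomness is drawn from R's RNG so runs are reproducible
// under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double transfer(double x, double beta, double x0, double rho,
                              double off) {
  double v = 1.0 / (1.0 + std::exp(-(x - x0) / rho)) - off;
  return v > 0.0 ? beta * v : 0.0;
}

// Multiplicative renormalization of a weight block to an exact target mean
// with per-weight cap (water-filling when the plain rescale would exceed
// the cap).  Operates on one row-slice of Wz given by column indices.
static void renorm_block(NumericMatrix& W, int row, int col0, int ncols,
                         double target, double wmax) {
  bool allzero = true;
  std::vector<bool> capped(ncols, false);
  for (int c = 0; c < ncols; ++c) {
    if (W(row, col0 + c) != 0.0) { allzero = false; break; }
  }
  if (allzero) return;
  for (int iter = 0; iter < ncols + 1; ++iter) {
    double s_free = 0.0;
    int n_capped = 0;
    for (int c = 0; c < ncols; ++c) {
      if (capped[c]) ++n_capped; else s_free += W(row, col0 + c);
    }
    if (s_free <= 0.0) break;
    double s = (target * ncols - wmax * n_capped) / s_free;
    bool newly = false;
    for (int c = 0; c < ncols; ++c) {
      if (!capped[c] && s * W(row, col0 + c) > wmax) {
        capped[c] = true;
        newly = true;
      }
    }
    if (!newly) {
      for (int c = 0; c < ncols; ++c) {
        if (capped[c]) W(row, col0 + c) = wmax;
        else W(row, col0 + c) *= s;
      }
      break;
    }
  }
}

// [[Rcpp::export]]
List simulate_trials_cpp(List params,
                         NumericMatrix EE, NumericMatrix EI,
                         NumericMatrix IE, NumericMatrix II,
                         NumericMatrix AEE, NumericMatrix AEI,
                         NumericMatrix AIE, NumericMatrix AII,
                         int N,
                         NumericMatrix Wz_init,
                         LogicalVector frozen,
                         IntegerVector trial_area,      // 1 = V1, 2 = S1
                         IntegerVector trial_location,  // 1 = bottom, 2 = top
                         IntegerVector trial_go,        // rewarded location
                         double alpha,
                         bool noise) {
  const double dt = as<double>(params["dt"]);
  const double tauE = as<double>(params["tau_E"]);
  const double tauI = as<double>(params["tau_I"]);
  const double beta = as<double>(params["beta"]);
  const double x0 = as<double>(params["x0"]);
  const double rho = as<double>(params["rho"]);
  const double sigr = as<double>(params["sigma_r"]);
  const double sigx = as<double>(params["sigma_x"]);
  const double sig = as<double>(params["sigma"]);
  const double theta0 = as<double>(params["theta0"]);
  const double gamma = as<double>(params["gamma"]);
  const double wmax = as<double>(params["W_max"]);
  const double wmean = as<double>(params["w_init_mean"]);
  const double cs = as<double>(params["c_s"]);
  const int n_isi = (int)std::lround(as<double>(params["t_isi"]) / dt);
  const int n_stim = (int)std::lround(as<double>(params["t_stim"]) / dt);

  const int NB = 8;           // area-subnetwork blocks
  const int NSRC = 6 * N;     // readout source columns (V1, S1, RL E units)
  const int n_trials = trial_area.size();
  const double off = 1.0 / (1.0 + std::exp(x0 / rho));
  const double sqdt = std::sqrt(dt);

  // sparse views of the aligned couplings (few nonzero entries per row)
  std::vector<std::vector<std::pair<int, double> > >
    aEE(NB), aEI(NB), aIE(NB), aII(NB);
  for (int b = 0; b < NB; ++b) {
    for (int j = 0; j < NB; ++j) {
      if (AEE(b, j) != 0.0) aEE[b].push_back(std::make_pair(j, AEE(b, j)));
      if (AEI(b, j) != 0.0) aEI[b].push_back(std::make_pair(j, AEI(b, j)));
      if (AIE(b, j) != 0.0) aIE[b].push_back(std::make_pair(j, AIE(b, j)));
      if (AII(b, j) != 0.0) aII[b].push_back(std::make_pair(j, AII(b, j)));
    }
  }

  std::vector<double> rE(NB * N, 0.0), xE(NB * N, 0.0), rI(NB * N, 0.0);
  std::vector<double> rEold(NB * N), rIold(NB * N);
  std::vector<double> SE(NB), SI(NB), baseE(NB), baseI(NB);

  NumericMatrix Wz = clone(Wz_init);

  IntegerVector out_action(n_trials), out_correct(n_trials),
    out_crossed(n_trials), out_chosen(n_trials);
  NumericVector out_dtime(n_trials), out_d1(n_trials), out_d2(n_trials);

  bool area_frozen[3];  // V1, S1, RL readout blocks
  for (int a = 0; a < 3; ++a) area_frozen[a] = frozen[a * 2 * N];

  double z[2] = {0.0, 0.0}, zpre[2] = {0.0, 0.0}, delta[2];

  for (int tr = 0; tr < n_trials; ++tr) {
    // fresh network state per trial; the ISI then provides a noisy baseline
    std::fill(rE.begin(), rE.end(), 0.0);
    std::fill(rI.begin(), rI.end(), 0.0);
    std::fill(xE.begin(), xE.end(), 0.0);
    int stim_block = (trial_area[tr] - 1) * 2 + (trial_location[tr] - 1);
    bool go_stim = trial_location[tr] == trial_go[tr];

    bool decided = false;
    int chosen = -1;
    double c_r = 0.0, dtime = NA_REAL;
    delta[0] = delta[1] = 0.0;

    for (int phase = 0; phase < 2; ++phase) {
      bool stim_on = phase == 1;
      int n_steps = stim_on ? n_stim : n_isi;
      for (int k = 0; k < n_steps; ++k) {
        // block sums from current rates
        for (int b = 0; b < NB; ++b) {
          double se = 0.0, si = 0.0;
          for (int u = 0; u < N; ++u) {
            se += rE[b * N + u];
            si += rI[b * N + u];
          }
          SE[b] = se;
          SI[b] = si;
        }
        for (int b = 0; b < NB; ++b) {
          double be = 0.0, bi = 0.0;
          for (int j = 0; j < NB; ++j) {
            be += EE(b, j) * SE[j] + EI(b, j) * SI[j];
            bi += IE(b, j) * SE[j] + II(b, j) * SI[j];
          }
          if (stim_on && b == stim_block) be += cs;  // stimulus to E only
          baseE[b] = be;
          baseI[b] = bi;
        }
        // rate updates from pre-update rates and noise states
        std::copy(rE.begin(), rE.end(), rEold.begin());
        std::copy(rI.begin(), rI.end(), rIold.begin());
        for (int b = 0; b < NB; ++b) {
          for (int u = 0; u < N; ++u) {
            int i = b * N + u;
            double de = baseE[b] + sigr * xE[i];
            for (size_t t = 0; t < aEE[b].size(); ++t)
              de += aEE[b][t].second * rEold[aEE[b][t].first * N + u];
            for (size_t t = 0; t < aEI[b].size(); ++t)
              de += aEI[b][t].second * rIold[aEI[b][t].first * N + u];
            rE[i] += dt / tauE * (-rE[i] + transfer(de, beta, x0, rho, off));
            double di = baseI[b];
            for (size_t t = 0; t < aIE[b].size(); ++t)
              di += aIE[b][t].second * rEold[aIE[b][t].first * N + u];
            for (size_t t = 0; t < aII[b].size(); ++t)
              di += aII[b][t].second * rIold[aII[b][t].first * N + u];
            rI[i] += dt / tauI * (-rI[i] + transfer(di, beta, x0, rho, off));
          }
        }
        if (noise) {
          for (int i = 0; i < NB * N; ++i) {
            xE[i] = xE[i] * (1.0 - dt) + sigx * sqdt * R::norm_rand();
          }
        } else {
          for (int i = 0; i < NB * N; ++i) xE[i] *= (1.0 - dt);
        }
        // readouts
        for (int i = 0; i < 2; ++i) {
          double acc = 0.0;
          for (int c = 0; c < NSRC; ++c) acc += Wz(i, c) * rE[c];
          z[i] = alpha * acc;
        }
        if (!stim_on) continue;

        // decision variables and threshold crossing
        for (int i = 0; i < 2; ++i) {
          delta[i] += z[i] * dt + (noise ? sig * sqdt * R::norm_rand() : 0.0);
        }
        if (!decided && (delta[0] >= theta0 || delta[1] >= theta0)) {
          decided = true;
          chosen = delta[0] >= delta[1] ? 0 : 1;
          dtime = (k + 1) * dt;
          bool dec_correct = (chosen == 0) ? go_stim : !go_stim;
          c_r = (dec_correct ? 1.0 : -1.0) * std::fabs(z[chosen] - zpre[chosen]);
        }
        // Hebbian update with reward-modified readout, clip, renormalize
        double zt[2] = { z[0], z[1] };
        if (decided) zt[chosen] += c_r;
        for (int i = 0; i < 2; ++i) {
          double g = gamma * dt * zt[i];
          if (g != 0.0) {
            for (int c = 0; c < NSRC; ++c) {
              if (frozen[c]) continue;
              double w = Wz(i, c) + g * rE[c];
              Wz(i, c) = w < 0.0 ? 0.0 : (w > wmax ? wmax : w);
            }
          }
        }
        for (int a = 0; a < 3; ++a) {
          if (area_frozen[a]) continue;
          for (int i = 0; i < 2; ++i) {
            renorm_block(Wz, i, a * 2 * N, 2 * N, wmean, wmax);
          }
        }
      }
      if (!stim_on) { zpre[0] = z[0]; zpre[1] = z[1]; }
    }

    bool go_action = decided && chosen == 0;
    out_action[tr] = go_action ? 1 : 0;
    out_correct[tr] = (go_action == go_stim) ? 1 : 0;
    out_crossed[tr] = decided ? 1 : 0;
    out_chosen[tr] = decided ? chosen + 1 : NA_INTEGER;
    out_dtime[tr] = dtime;
    out_d1[tr] = delta[0];
    out_d2[tr] = delta[1];
  }

  NumericMatrix rE_out(N, NB), xE_out(N, NB), rI_out(N, NB);
  for (int b = 0; b < NB; ++b) {
    for (int u = 0; u < N; ++u) {
      rE_out(u, b) = rE[b * N + u];
      xE_out(u, b) = xE[b * N + u];
      rI_out(u, b) = rI[b * N + u];
    }
  }
  return List::create(
    _["action"] = out_action, _["correct"] = out_correct,
    _["crossed"] = out_crossed, _["chosen"] = out_chosen,
    _["decision_time"] = out_dtime,
    _["delta1"] = out_d1, _["delta2"] = out_d2,
    _["W_z"] = Wz, _["rE"] = rE_out, _["xE"] = xE_out,
    _["rI"] = rI_out);
}
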