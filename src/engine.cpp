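#include <Rcpp.h>
using namespace Rcpp;

// Full simulation engine for one realization.
//
// Time is organised in periods: each period consists of `events_per_period`
// elementary imitation events (a random ordered pair (i, j); j adopts i's
// strategy with the Fermi probability), after which every player's score is
// refreshed by the scoring rule and all groups are re-formed by score ranking
// with random tie-breaking. One full Monte Carlo step spans n elementary
// events, so with events_per_period = 1 a Monte Carlo step comprises n
// periods, and with events_per_period = n it comprises exactly one.
//
// RNG consumption per operation is fixed (three uniforms per event; n for a
// hybrid mask when 0 < p < 1; n for tie-breaking) so the pure-R mirror used
// in tests can reproduce the stream bit-for-bit.
//
// Scoring: image compares a player's own contribution with the average
// contribution; group scoring compares the player's group total with the
// same average, so a group scores 1 whenever it contributed visibly at all.
// Ties retain the previous score in both rules.
//
// The cooperator fraction is recorded once per full Monte Carlo step;
// monomorphic states are absorbing and are padded without further RNG use.
// [[Rcpp::export]]
List simulate_run_cpp(IntegerVector strategies0, IntegerVector scores0,
                      IntegerVector groups0, int k, int s, double r, double K,
                      double p_image, int mc_steps, int events_per_period,
                      bool record_classes) {
  const int n = k * s;
  std::vector<int> strat(strategies0.begin(), strategies0.end());
  std::vector<int> score(scores0.begin(), scores0.end());
  std::vector<int> grp(n);
  for (int a = 0; a < n; ++a) grp[a] = groups0[a] - 1;

  std::vector<double> pot(k, 0.0);
  int totC = 0;
  for (int a = 0; a < n; ++a) { pot[grp[a]] += strat[a]; totC += strat[a]; }
  const double rs = r / (double) s;

  NumericVector traj(mc_steps + 1);
  traj[0] = totC / (double) n;
  NumericMatrix cls(record_classes ? mc_steps + 1 : 0, 4);
  std::vector<double> u(n);
  std::vector<int> idx(n);
  int absorbed_at = -1;

  if (record_classes) {
    int c1 = 0, d1 = 0, c0 = 0;
    for (int a = 0; a < n; ++a) {
      if (strat[a] && score[a]) ++c1;
      else if (!strat[a] && score[a]) ++d1;
      else if (strat[a]) ++c0;
    }
    cls(0, 0) = c1 / (double) n; cls(0, 1) = d1 / (double) n;
    cls(0, 2) = c0 / (double) n;
    cls(0, 3) = (n - c1 - d1 - c0) / (double) n;
  }

  int since_update = 0;
  for (int step = 0; step < mc_steps; ++step) {
    if (totC == 0 || totC == n) {
      if (absorbed_at < 0) absorbed_at = step;
      for (int t2 = step; t2 < mc_steps; ++t2) {
        traj[t2 + 1] = traj[t2];
        if (record_classes)
          for (int c = 0; c < 4; ++c) cls(t2 + 1, c) = cls(t2, c);
      }
      break;
    }
    for (int ev = 0; ev < n; ++ev) {
      // one elementary imitation event
      double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
      int i = (int) (u1 * n);       if (i > n - 1) i = n - 1;
      int j = (int) (u2 * (n - 1)); if (j > n - 2) j = n - 2;
      if (j >= i) ++j;
      double phi_i = (1.0 - strat[i]) + rs * pot[grp[i]];
      double phi_j = (1.0 - strat[j]) + rs * pot[grp[j]];
      double w = 1.0 / (1.0 + std::exp((phi_j - phi_i) / K));
      if (u3 < w && strat[j] != strat[i]) {
        pot[grp[j]] += strat[i] - strat[j];
        totC += strat[i] - strat[j];
        strat[j] = strat[i];
      }
      if (++since_update == events_per_period) {
        since_update = 0;
        // rescore everyone
        double cbar = totC / (double) n;
        if (p_image >= 1.0) {
          for (int a = 0; a < n; ++a)
            score[a] = strat[a] > cbar ? 1 : (strat[a] < cbar ? 0 : score[a]);
        } else if (p_image <= 0.0) {
          for (int a = 0; a < n; ++a) {
            double gt = pot[grp[a]];
            score[a] = gt > cbar ? 1 : (gt < cbar ? 0 : score[a]);
          }
        } else {
          for (int a = 0; a < n; ++a) {
            double um = unif_rand();
            if (um < p_image)
              score[a] = strat[a] > cbar ? 1 : (strat[a] < cbar ? 0 : score[a]);
            else {
              double gt = pot[grp[a]];
              score[a] = gt > cbar ? 1 : (gt < cbar ? 0 : score[a]);
            }
          }
        }
        // rematch by score rank, random tie-break
        for (int a = 0; a < n; ++a) { u[a] = unif_rand(); idx[a] = a; }
        std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
          if (score[a] != score[b]) return score[a] > score[b];
          return u[a] < u[b];
        });
        for (int pos = 0; pos < n; ++pos) grp[idx[pos]] = pos / s;
        std::fill(pot.begin(), pot.end(), 0.0);
        for (int a = 0; a < n; ++a) pot[grp[a]] += strat[a];
      }
      if (totC == 0 || totC == n) break;   // no further events can change it
    }
    traj[step + 1] = totC / (double) n;
    if (record_classes) {
      int c1 = 0, d1 = 0, c0 = 0;
      for (int a = 0; a < n; ++a) {
        if (strat[a] && score[a]) ++c1;
        else if (!strat[a] && score[a]) ++d1;
        else if (strat[a]) ++c0;
      }
      cls(step + 1, 0) = c1 / (double) n; cls(step + 1, 1) = d1 / (double) n;
      cls(step + 1, 2) = c0 / (double) n;
      cls(step + 1, 3) = (n - c1 - d1 - c0) / (double) n;
    }
    if ((totC == 0 || totC == n) && absorbed_at < 0) absorbed_at = step + 1;
  }

  IntegerVector strat_out(strat.begin(), strat.end());
  IntegerVector score_out(score.begin(), score.end());
  IntegerVector grp_out(n);
  for (int a = 0; a < n; ++a) grp_out[a] = grp[a] + 1;
  return List::create(_["trajectory"] = traj,
                      _["class_fractions"] = cls,
                      _["strategies"] = strat_out,
                      _["scores"] = score_out,
                      _["groups"] = grp_out,
                      _["absorbed_at"] = absorbed_at);
}
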