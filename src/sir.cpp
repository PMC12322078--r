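#include <Rcpp.h>
using namespace Rcpp;

// Agent-count SIR propagation on a weighted network.
//
// Per step and region: (1) synthesis of normal agents, binomial on the
// region size; (2) clearance of normal and misfolded agents; (3) density-
// dependent misfolding of normal agents; (4) migration of each agent with
// probability `mobility` to a neighbour chosen proportionally to edge
// weight; (5) atrophy accrual from the misfolded fraction (k1) plus the
// weighted mean of the neighbours' previous-step atrophy increment (k2),
// capped so cumulative atrophy stays within [0, 1]. All randomness comes
// from R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".sir_core")]]
List sir_core(NumericMatrix W, NumericVector sizes, int seed_region,
              int n_steps, double synthesis_rate, double clearance_normal,
              double clearance_misfolded, double trans_rate, double mobility,
              int injection_count, double k1, double k2) {
  const int n = W.nrow();
  std::vector< std::vector<int> > nbr(n);
  std::vector< std::vector<double> > cum(n);
  std::vector<double> C(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j != i && W(i, j) > 0) { nbr[i].push_back(j); C[i] += W(i, j); }
    }
    double acc = 0.0;
    for (size_t k = 0; k < nbr[i].size(); ++k) {
      acc += W(i, nbr[i][k]) / C[i];
      cum[i].push_back(acc);
    }
    if (!cum[i].empty()) cum[i].back() = 1.0;
  }

  std::vector<int> normal(n, 0), mis(n, 0), in_normal(n), in_mis(n);
  mis[seed_region] = injection_count;
  std::vector<double> atrophy(n, 0.0), inc_prev(n, 0.0), inc_cur(n, 0.0);

  IntegerMatrix normal_out(n_steps, n), mis_out(n_steps, n);
  NumericMatrix atrophy_out(n_steps, n);
  NumericVector synth_log(n_steps), clear_log(n_steps);

  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    double synthesized = 0.0, cleared = 0.0;
    for (int i = 0; i < n; ++i) {
      // 1. synthesis: one trial per size unit of the region
      int trials = (int) std::floor(sizes[i] + 0.5);
      int s = (trials > 0) ? (int) R::rbinom(trials, synthesis_rate) : 0;
      normal[i] += s;
      synthesized += s;
      // 2. clearance
      int cn = (normal[i] > 0) ? (int) R::rbinom(normal[i], clearance_normal) : 0;
      int cm = (mis[i] > 0) ? (int) R::rbinom(mis[i], clearance_misfolded) : 0;
      normal[i] -= cn;
      mis[i] -= cm;
      cleared += cn + cm;
      // 3. conversion: each normal agent misfolds with prob
      //    1 - (1 - trans_rate)^(misfolded density)
      if (normal[i] > 0 && mis[i] > 0 && trans_rate > 0) {
        double density = mis[i] / sizes[i];
        double p_conv = 1.0 - std::pow(1.0 - trans_rate, density);
        int conv = (int) R::rbinom(normal[i], p_conv);
        normal[i] -= conv;
        mis[i] += conv;
      }
    }
    // 4. migration (simultaneous across regions)
    std::fill(in_normal.begin(), in_normal.end(), 0);
    std::fill(in_mis.begin(), in_mis.end(), 0);
    if (mobility > 0) {
      for (int i = 0; i < n; ++i) {
        if (cum[i].empty()) continue;  // isolated region: agents stay
        int mv_n = (normal[i] > 0) ? (int) R::rbinom(normal[i], mobility) : 0;
        int mv_m = (mis[i] > 0) ? (int) R::rbinom(mis[i], mobility) : 0;
        normal[i] -= mv_n;
        mis[i] -= mv_m;
        for (int a = 0; a < mv_n + mv_m; ++a) {
          double u = R::unif_rand();
          size_t k = 0;
          while (k + 1 < cum[i].size() && u > cum[i][k]) ++k;
          if (a < mv_n) in_normal[nbr[i][k]]++; else in_mis[nbr[i][k]]++;
        }
      }
      for (int i = 0; i < n; ++i) { normal[i] += in_normal[i]; mis[i] += in_mis[i]; }
    }
    // 5. atrophy accrual, capped at 1
    for (int i = 0; i < n; ++i) {
      int tot = normal[i] + mis[i];
      double frac = (tot > 0) ? (double) mis[i] / tot : 0.0;
      double deaff = 0.0;
      if (k2 > 0 && C[i] > 0) {
        for (size_t k = 0; k < nbr[i].size(); ++k) {
          deaff += W(i, nbr[i][k]) / C[i] * inc_prev[nbr[i][k]];
        }
      }
      double inc = k1 * frac + k2 * deaff;
      if (inc > 1.0 - atrophy[i]) inc = 1.0 - atrophy[i];
      if (inc < 0.0) inc = 0.0;
      atrophy[i] += inc;
      inc_cur[i] = inc;
    }
    std::swap(inc_prev, inc_cur);
    for (int i = 0; i < n; ++i) {
      normal_out(t, i) = normal[i];
      mis_out(t, i) = mis[i];
      atrophy_out(t, i) = atrophy[i];
    }
    synth_log[t] = synthesized;
    clear_log[t] = cleared;
  }
  return List::create(_["normal_counts"] = normal_out,
                      _["misfolded_counts"] = mis_out,
                      _["simulated_atrophy"] = atrophy_out,
                      _["synthesized"] = synth_log,
                      _["cleared"] = clear_log);
}
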