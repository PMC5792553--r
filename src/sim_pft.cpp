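#include <Rcpp.h>
using namespace Rcpp;

// Daily surrogate GPP/phenology kernel for ONE plant functional type over
// many grid cells. All parameter semantics follow the optimisable parameter
// table; all fixed structural constants come in through `consts` (see
// surrogate_config()). The R-level step_phenology(), spin_up() and
// simulate() wrappers are thin shells around this single implementation.
//
// Phase codes: 0 dormant, 1 growth, 2 mature, 3 senescent.

static inline double tent(double T, double tmin, double topt, double tmax) {
  if (T <= tmin || T >= tmax) return 0.0;
  if (T <= topt) return (T - tmin) / (topt - tmin);
  return (tmax - T) / (tmax - topt);
}

// [[Rcpp::export(name = ".sim_pft_core")]]
List sim_pft_core(NumericMatrix tair, NumericMatrix sw, NumericMatrix sm,
                  IntegerVector doy, NumericVector lat, List par,
                  List traits, List consts, List state0,
                  bool keep_lai) {
  const int ncell = tair.nrow(), nday = tair.ncol();

  // --- parameters (fixed defaults where not applicable to this PFT) ---
  const double vcmax = as<double>(par["vcmax"]);
  const double gs_slope = as<double>(par["gs_slope"]);
  const double t_opt = as<double>(par["t_opt"]);
  const double t_min = as<double>(par["t_min"]);
  const double t_max = as<double>(par["t_max"]);
  const double f_stress_h = as<double>(par["f_stress_h"]);
  const double sla = as<double>(par["sla"]);
  const double lai_max = as<double>(par["lai_max"]);
  const double k_lai_happy = as<double>(par["k_lai_happy"]);
  const double k_pheno_crit = as<double>(par["k_pheno_crit"]);
  const double m_tmin = as<double>(par["m_tmin"]);
  const double l_age_crit = as<double>(par["l_age_crit"]);
  const double t_senes = as<double>(par["t_senes"]);
  const double m_senes = as<double>(par["m_senes_nosenes"]);
  const double l_fall = as<double>(par["l_fall"]);

  if (!(t_min < t_opt && t_opt < t_max))
    stop("temperature response requires t_min < t_opt < t_max");

  const bool evergreen = as<bool>(traits["evergreen"]);
  const bool trig_temp = as<bool>(traits["trig_temp"]);
  const bool trig_moist = as<bool>(traits["trig_moist"]);

  const double c_day = as<double>(consts["c_day"]);
  const double g0 = as<double>(consts["g0"]);
  const double k_ext = as<double>(consts["k_ext"]);
  const double R_half = as<double>(consts["R_half"]);
  const double gdd_base = as<double>(consts["gdd_base"]);
  const double gdd_ref = as<double>(consts["gdd_ref"]);
  const double B_day = as<double>(consts["B_day"]);
  const double r_grow = as<double>(consts["r_grow"]);
  const double lai_dormant = as<double>(consts["lai_dormant"]);
  const int senes_window = as<int>(consts["senes_window"]);
  const int min_growing_days = as<int>(consts["min_growing_days"]);
  const int sh_shift = as<int>(consts["sh_shift"]);

  // --- state (copied; caller keeps ownership of state0) ---
  NumericVector lai = clone(as<NumericVector>(state0["lai"]));
  NumericVector age = clone(as<NumericVector>(state0["mean_leaf_age"]));
  NumericVector gdd = clone(as<NumericVector>(state0["gdd"]));
  NumericVector dsmm = clone(as<NumericVector>(state0["days_since_moisture_min"]));
  NumericVector wmin = clone(as<NumericVector>(state0["wmin"]));
  IntegerVector phase = clone(as<IntegerVector>(state0["phase"]));
  LogicalVector reserve = clone(as<LogicalVector>(state0["reserve_flag"]));
  LogicalVector onset_done = clone(as<LogicalVector>(state0["onset_done"]));
  IntegerVector days_in_phase = clone(as<IntegerVector>(state0["days_in_phase"]));

  NumericMatrix gpp(ncell, nday);
  NumericMatrix lai_out = keep_lai ? NumericMatrix(ncell, nday)
                                   : NumericMatrix(0, 0);

  // running sums over the senescence window (O(1) per cell-day)
  std::vector<double> tsum(ncell, 0.0), wsum(ncell, 0.0);

  for (int t = 0; t < nday; ++t) {
    const int w0 = std::max(0, t - senes_window + 1);
    const double wlen = double(t - w0 + 1);
    for (int i = 0; i < ncell; ++i) {
      tsum[i] += tair(i, t);
      wsum[i] += sm(i, t);
      if (t >= senes_window) {
        tsum[i] -= tair(i, t - senes_window);
        wsum[i] -= sm(i, t - senes_window);
      }
    }
    for (int i = 0; i < ncell; ++i) {
      const double T = tair(i, t), R = sw(i, t), W = sm(i, t);
      if (W < -1e-9 || W > 1 + 1e-9)
        stop("soil moisture outside [0, 1]");
      if (R < -1e-9) stop("negative shortwave flux");

      // phenological year origin: day-of-year 1 in the north, shifted by
      // sh_shift days in the southern hemisphere
      int edoy = doy[t];
      if (lat[i] < 0) edoy = ((doy[t] - 1 + sh_shift) % 365) + 1;
      if (edoy == 1) {            // new phenological year: reset counters
        gdd[i] = 0.0;
        wmin[i] = W;
        dsmm[i] = 0.0;
        onset_done[i] = false;
      }
      gdd[i] += std::max(0.0, T - gdd_base);
      if (W <= wmin[i] + 1e-12) { wmin[i] = W; dsmm[i] = 0.0; }
      else dsmm[i] += 1.0;

      if (evergreen) {
        // no onset/senescence: growth toward lai_max against an age-driven
        // turnover lai / l_age_crit
        double g = r_grow * sla * B_day;
        if (lai[i] >= k_lai_happy * lai_max) g *= 0.5;
        const double turn = lai[i] / l_age_crit;
        const double base = std::max(lai[i] - turn, 0.0);
        double lai_new = std::min(lai_max, lai[i] + g - turn);
        if (lai_new < 0) lai_new = 0;
        const double grown = std::max(0.0, lai_new - base);
        age[i] = lai_new > 1e-9
          ? (base * (age[i] + 1.0) + grown * 0.0) / (base + grown)
          : 0.0;
        lai[i] = lai_new;
        phase[i] = 2;
      } else {
        switch (phase[i]) {
        case 0: {                 // dormant
          bool on = false;
          if (!onset_done[i]) {
            if (trig_temp && gdd[i] > k_pheno_crit * gdd_ref) on = true;
            if (trig_moist && dsmm[i] > m_tmin) on = true;
          }
          if (on) {
            phase[i] = 1; reserve[i] = true; onset_done[i] = true;
            age[i] = 0.0; days_in_phase[i] = 0;
          }
          break;
        }
        case 1: {                 // growth
          double g = r_grow * sla * B_day;
          if (!reserve[i]) g *= 0.5;
          double lai_new = std::min(lai_max, lai[i] + g);
          age[i] = lai_new > 1e-9 ? (lai[i] * (age[i] + 1.0)) / lai_new : 0.0;
          lai[i] = lai_new;
          if (lai[i] >= k_lai_happy * lai_max) reserve[i] = false;
          days_in_phase[i] += 1;
          if (lai[i] >= lai_max - 1e-9) { phase[i] = 2; }
          break;
        }
        case 2:                   // mature
          age[i] += 1.0;
          days_in_phase[i] += 1;
          break;
        case 3: {                 // senescent
          lai[i] *= (1.0 - l_fall);
          age[i] += 1.0;
          if (lai[i] < lai_dormant) {
            phase[i] = 0; lai[i] = 0.0; age[i] = 0.0;
            reserve[i] = false; days_in_phase[i] = 0;
          }
          break;
        }
        }
        // senescence trigger from growth or mature, once the canopy has
        // been out long enough to avoid spring flapping
        if ((phase[i] == 1 || phase[i] == 2) &&
            days_in_phase[i] >= min_growing_days) {
          const double t7 = tsum[i] / wlen, w7 = wsum[i] / wlen;
          bool sen = false;
          if (trig_temp && t7 < t_senes) sen = true;
          if (trig_moist && w7 < m_senes) sen = true;
          if (sen) { phase[i] = 3; days_in_phase[i] = 0; }
        }
      }

      // --- daily GPP (skip the transcendental when the canopy is bare) ---
      if (lai[i] > 0.0) {
        const double f_T = tent(T, t_min, t_opt, t_max);
        const double f_W = std::min(1.0, std::max(0.0, 1.0 - f_stress_h * (1.0 - W)));
        const double f_R = R / (R + R_half);
        const double f_L = 1.0 - std::exp(-k_ext * lai[i]);
        const double f_age = std::max(0.0, 1.0 - age[i] / (2.0 * l_age_crit));
        const double A_c = c_day * vcmax * f_T * f_R * f_L * f_age;
        const double A_w = g0 * gs_slope * W * f_L;
        gpp(i, t) = std::min(A_c, A_w) * f_W;
      }
      if (keep_lai) lai_out(i, t) = lai[i];
    }
  }

  List state = List::create(
    _["lai"] = lai, _["mean_leaf_age"] = age, _["gdd"] = gdd,
    _["days_since_moisture_min"] = dsmm, _["wmin"] = wmin,
    _["phase"] = phase, _["reserve_flag"] = reserve,
    _["onset_done"] = onset_done, _["days_in_phase"] = days_in_phase);
  return List::create(_["gpp"] = gpp, _["state"] = state,
                      _["lai"] = lai_out);
}
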