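#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event indices into the nine-channel event table:
// 0 sensitive birth, 1 sensitive death, 2 missegregation (a += 1),
// 3 sensitive mutation (m += 1), 4 aneuploid birth, 5 aneuploid death,
// 6 aneuploid mutation (m += 1), 7 mutant birth, 8 mutant death.
// Missegregation and mutation leave the parent count unchanged: the
// dividing cell produces one daughter of the new type.

static inline void compute_rates(double s, double a, double m,
                                 double lambda_s, double mu_s,
                                 double lambda_a, double mu_a,
                                 double lambda_m, double mu_m,
                                 double u, double v, double v_a,
                                 double K, bool exact_factors,
                                 double *rates) {
  double crowd = 0.0;
  if (R_finite(K) && K > 0) crowd = (s + a + m) / K;
  rates[0] = lambda_s * s * (exact_factors ? (1.0 - u - v) : 1.0);
  rates[1] = (mu_s + lambda_s * crowd) * s;
  rates[2] = u * lambda_s * s;
  rates[3] = v * lambda_s * s;
  rates[4] = lambda_a * a * (exact_factors ? (1.0 - v_a) : 1.0);
  rates[5] = (mu_a + lambda_a * crowd) * a;
  rates[6] = v_a * lambda_a * a;
  rates[7] = lambda_m * m;
  rates[8] = (mu_m + lambda_m * crowd) * m;
}

// pick a mutant lineage index proportional to current lineage size
static inline int pick_lineage(const std::vector<double> &sizes, double m_tot) {
  double x = unif_rand() * m_tot;
  double acc = 0.0;
  for (size_t i = 0; i < sizes.size(); ++i) {
    acc += sizes[i];
    if (x < acc) return (int)i;
  }
  // roundoff fallback: last nonempty lineage
  for (size_t i = sizes.size(); i-- > 0;) if (sizes[i] > 0) return (int)i;
  return -1;
}

// [[Rcpp::export]]
List ssa_run_cpp(double lambda_s, double mu_s, double lambda_a, double mu_a,
                 double lambda_m, double mu_m, double u, double v, double v_a,
                 double K, bool exact_factors,
                 double s0, double a0, double m0,
                 double est_threshold, double recurrence_target,
                 double detection_target,
                 double max_time, double max_events, double record_interval) {
  double s = s0, a = a0, m = m0, t = 0.0;
  bool rec_on = R_finite(recurrence_target) && recurrence_target > 0;
  bool det_on = R_finite(detection_target) && detection_target > 0;
  bool record_all = !(record_interval > 0);

  std::vector<double> rt, rs_, ra_, rm_;
  rt.push_back(t); rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
  double next_record = record_interval;

  std::vector<double> lin_size, lin_born;   // per mutant-lineage bookkeeping
  double rates[9];
  double ev_counts[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  double n_events = 0.0;

  bool established = (est_threshold > 0) && (m >= est_threshold);
  double establish_time = NA_REAL, rescue_time = NA_REAL;
  double recurrence_time = NA_REAL, detection_time = NA_REAL;
  double first_mutant_time = (m0 > 0) ? 0.0 : NA_REAL;
  if (m0 > 0) { lin_size.push_back(m0); lin_born.push_back(0.0); }

  int outcome = 3; // censored unless a terminating condition fires

  while (true) {
    if (s == 0 && a == 0 && m == 0) { outcome = 0; break; }
    bool done = established &&
      (!rec_on || R_finite(recurrence_time)) &&
      (!det_on || R_finite(detection_time));
    if (done) { outcome = rec_on ? 2 : 1; break; }
    if (n_events >= max_events) { outcome = 3; break; }

    compute_rates(s, a, m, lambda_s, mu_s, lambda_a, mu_a, lambda_m, mu_m,
                  u, v, v_a, K, exact_factors, rates);
    double total = 0.0;
    for (int k = 0; k < 9; ++k) total += rates[k];
    if (total <= 0.0) { outcome = 3; break; } // absorbing nonzero state
    double dt = exp_rand() / total;
    if (t + dt > max_time) { t = max_time; outcome = 3; break; }
    t += dt;

    double x = unif_rand() * total;
    int k = 0;
    double acc = rates[0];
    while (x >= acc && k < 8) { acc += rates[++k]; }
    ++ev_counts[k];
    ++n_events;

    switch (k) {
      case 0: s += 1; break;
      case 1: s -= 1; break;
      case 2: a += 1; break;
      case 3: case 6: {
        m += 1;
        lin_size.push_back(1.0);
        lin_born.push_back(t);
        if (!R_finite(first_mutant_time)) first_mutant_time = t;
        break;
      }
      case 4: a += 1; break;
      case 5: a -= 1; break;
      case 7: {
        int i = pick_lineage(lin_size, m);
        if (i >= 0) lin_size[i] += 1;
        m += 1;
        break;
      }
      case 8: {
        int i = pick_lineage(lin_size, m);
        if (i >= 0) lin_size[i] -= 1;
        m -= 1;
        break;
      }
    }

    if (!established && est_threshold > 0 && m >= est_threshold) {
      established = true;
      establish_time = t;
      // rescue time: birth time of the earliest still-surviving mutant
      // lineage, i.e. the lineage that went on to establish
      double tmin = R_PosInf;
      for (size_t i = 0; i < lin_size.size(); ++i) {
        if (lin_size[i] > 0 && lin_born[i] < tmin) tmin = lin_born[i];
      }
      rescue_time = R_finite(tmin) ? tmin : t;
    }
    if (det_on && !R_finite(detection_time) && m >= detection_target)
      detection_time = t;
    if (rec_on && !R_finite(recurrence_time) && m >= recurrence_target)
      recurrence_time = t;

    if (record_all) {
      rt.push_back(t); rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
    } else {
      while (t >= next_record && next_record <= max_time) {
        rt.push_back(next_record);
        rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
        next_record += record_interval;
      }
    }
  }

  if (rt.back() != t) {
    rt.push_back(t); rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
  }

  return List::create(
    _["time"] = rt, _["s"] = rs_, _["a"] = ra_, _["m"] = rm_,
    _["outcome"] = outcome,
    _["rescue_time"] = rescue_time,
    _["establish_time"] = establish_time,
    _["recurrence_time"] = recurrence_time,
    _["detection_time"] = detection_time,
    _["first_mutant_time"] = first_mutant_time,
    _["t_end"] = t,
    _["n_events"] = n_events,
    _["event_counts"] = NumericVector(ev_counts, ev_counts + 9),
    _["final"] = NumericVector::create(s, a, m));
}

// Tau-leaping: fixed step, Poisson event counts per channel, counts clamped
// at zero after each leap. No lineage tracking: rescue_time is reported as
// the establishment-threshold crossing time.
// [[Rcpp::export]]
List tau_leap_run_cpp(double lambda_s, double mu_s, double lambda_a,
                      double mu_a, double lambda_m, double mu_m,
                      double u, double v, double v_a,
                      double K, bool exact_factors,
                      double s0, double a0, double m0, double step,
                      double est_threshold, double recurrence_target,
                      double detection_target,
                      double max_time, double max_events,
                      double record_interval) {
  double s = s0, a = a0, m = m0, t = 0.0;
  bool rec_on = R_finite(recurrence_target) && recurrence_target > 0;
  bool det_on = R_finite(detection_target) && detection_target > 0;
  bool record_all = !(record_interval > 0);

  std::vector<double> rt, rs_, ra_, rm_;
  rt.push_back(t); rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
  double next_record = record_interval;

  double rates[9];
  double ev_counts[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  double n_events = 0.0;
  bool established = (est_threshold > 0) && (m >= est_threshold);
  double establish_time = NA_REAL, recurrence_time = NA_REAL,
         detection_time = NA_REAL, first_mutant_time = (m0 > 0) ? 0.0 : NA_REAL;
  int outcome = 3;

  while (true) {
    if (s == 0 && a == 0 && m == 0) { outcome = 0; break; }
    bool done = established &&
      (!rec_on || R_finite(recurrence_time)) &&
      (!det_on || R_finite(detection_time));
    if (done) { outcome = rec_on ? 2 : 1; break; }
    if (t >= max_time || n_events >= max_events) { outcome = 3; break; }

    compute_rates(s, a, m, lambda_s, mu_s, lambda_a, mu_a, lambda_m, mu_m,
                  u, v, v_a, K, exact_factors, rates);
    double kdraw[9];
    for (int k = 0; k < 9; ++k) {
      kdraw[k] = (rates[k] > 0) ? R::rpois(rates[k] * step) : 0.0;
      ev_counts[k] += kdraw[k];
      n_events += kdraw[k];
    }
    s += kdraw[0] - kdraw[1];
    a += kdraw[2] + kdraw[4] - kdraw[5];
    m += kdraw[3] + kdraw[6] + kdraw[7] - kdraw[8];
    if (s < 0) s = 0;
    if (a < 0) a = 0;
    if (m < 0) m = 0;
    t += step;

    if (!R_finite(first_mutant_time) && m > 0) first_mutant_time = t;
    if (!established && est_threshold > 0 && m >= est_threshold) {
      established = true;
      establish_time = t;
    }
    if (det_on && !R_finite(detection_time) && m >= detection_target)
      detection_time = t;
    if (rec_on && !R_finite(recurrence_time) && m >= recurrence_target)
      recurrence_time = t;

    if (record_all) {
      rt.push_back(t); rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
    } else {
      while (t >= next_record && next_record <= max_time) {
        rt.push_back(next_record);
        rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
        next_record += record_interval;
      }
    }
  }

  if (rt.back() != t) {
    rt.push_back(t); rs_.push_back(s); ra_.push_back(a); rm_.push_back(m);
  }

  return List::create(
    _["time"] = rt, _["s"] = rs_, _["a"] = ra_, _["m"] = rm_,
    _["outcome"] = outcome,
    _["rescue_time"] = establish_time,
    _["establish_time"] = establish_time,
    _["recurrence_time"] = recurrence_time,
    _["detection_time"] = detection_time,
    _["first_mutant_time"] = first_mutant_time,
    _["t_end"] = t,
    _["n_events"] = n_events,
    _["event_counts"] = NumericVector(ev_counts, ev_counts + 9),
    _["final"] = NumericVector::create(s, a, m));
}
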