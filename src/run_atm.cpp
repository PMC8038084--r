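#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Optimized run loop for the ant-trail model.
//
// Stage I: all velocities from time-t occupancy/pheromone (parallel update),
// then all positions advance. Stage II: evaporation, then deposition using
// the time-t occupancy and Stage-I velocities. Then injection at cell 0.
//
// RNG contract (must match the R reference stepper bit-for-bit): one
// unif_rand() per ant in ascending id order, consumed iff the
// meager-pheromone case applies (next cell empty, sigma < 1), then one
// unif_rand() per step for injection. v_avg accumulates in long double to
// match R's sum().

// [[Rcpp::export]]
List run_atm_cpp(int L, double re, double tau, double sigma_sat,
                 double vmin, double a, double P, double inflow,
                 double max_steps, bool deposit_requires_motion,
                 bool record_trajectory) {
  std::vector<double> pher((size_t)L, 0.0);
  std::vector<int> occ((size_t)L, -1);
  std::vector<double> pos, vel;
  pos.reserve((size_t)L);
  vel.reserve((size_t)L);
  pos.push_back(0.0);
  vel.push_back(vmin);
  occ[0] = 0;
  int N = 1;

  std::vector<double> m_t, m_n, m_d, m_v, m_f;
  List traj_pos, traj_vel, traj_pher;
  std::string termination = "max_steps";
  double steps_done = 0.0;

  GetRNGstate();
  for (double t = 1.0; t <= max_steps; t += 1.0) {
    int n0 = N;
    std::vector<double> newvel((size_t)n0);
    std::vector<int> oldcell((size_t)n0);

    // Stage I: velocities in parallel from time-t state
    for (int j = 0; j < n0; ++j) {
      int c = (int)pos[(size_t)j];
      oldcell[(size_t)j] = c;
      int nc = c + 1;
      if (nc == L) nc = 0;
      double v;
      if (occ[(size_t)nc] != -1) {
        v = 0.0;
      } else {
        double s = pher[(size_t)nc];
        if (s < 1.0) {
          double u = unif_rand();
          double prev = vel[(size_t)j] > 0.0 ? vel[(size_t)j] : vmin;
          if (u < P) {
            v = prev - 0.1;
            if (v < vmin) v = vmin;
          } else {
            v = prev;
          }
        } else if (s < sigma_sat) {
          v = vmin + a * s;
        } else {
          v = vmin + a * sigma_sat;
        }
      }
      newvel[(size_t)j] = v;
    }

    // advance all positions; rebuild occupancy, checking exclusion
    for (int j = 0; j < n0; ++j) occ[(size_t)oldcell[(size_t)j]] = -1;
    for (int j = 0; j < n0; ++j) {
      double p = pos[(size_t)j] + newvel[(size_t)j];
      if (p >= (double)L) p -= (double)L;
      pos[(size_t)j] = p;
      int c = (int)p;
      if (occ[(size_t)c] != -1) {
        PutRNGstate();
        stop("internal consistency failure: two ants map to one cell");
      }
      occ[(size_t)c] = j;
    }

    // per-step metrics from pre-injection population
    long double vsum = 0.0L;
    for (int j = 0; j < n0; ++j) vsum += newvel[(size_t)j];
    // round the long-double accumulator to double before dividing, as R's
    // sum()/n does, so reference and optimized metrics agree bit-for-bit
    double v_avg = (double)vsum / (double)n0;
    double density = (double)n0 / (double)L;
    double flow = density * v_avg;

    // Stage II: evaporation then deposition (time-t occupancy)
    for (int i = 0; i < L; ++i)
      if (pher[(size_t)i] > 0.0) pher[(size_t)i] *= (1.0 - re);
    for (int j = 0; j < n0; ++j) {
      int c = oldcell[(size_t)j];
      if (pher[(size_t)c] >= sigma_sat) {
        pher[(size_t)c] = sigma_sat;
      } else if (!deposit_requires_motion || newvel[(size_t)j] > 0.0) {
        double s2 = pher[(size_t)c] + tau;
        pher[(size_t)c] = s2 > sigma_sat ? sigma_sat : s2;
      }
      vel[(size_t)j] = newvel[(size_t)j];
    }

    // injection draw is consumed every step
    double u = unif_rand();
    if (occ[0] == -1 && u < inflow) {
      pos.push_back(0.0);
      vel.push_back(vmin);
      occ[0] = N;
      ++N;
    }

    m_t.push_back(t);
    m_n.push_back((double)n0);
    m_d.push_back(density);
    m_v.push_back(v_avg);
    m_f.push_back(flow);
    if (record_trajectory) {
      traj_pos.push_back(NumericVector(pos.begin(), pos.end()));
      traj_vel.push_back(NumericVector(vel.begin(), vel.end()));
      traj_pher.push_back(NumericVector(pher.begin(), pher.end()));
    }
    steps_done = t;
    if (N == L) {
      termination = "density_reached";
      break;
    }
  }
  PutRNGstate();

  List out = List::create(
      _["t"] = NumericVector(m_t.begin(), m_t.end()),
      _["n_ants"] = NumericVector(m_n.begin(), m_n.end()),
      _["density"] = NumericVector(m_d.begin(), m_d.end()),
      _["v_avg"] = NumericVector(m_v.begin(), m_v.end()),
      _["flow"] = NumericVector(m_f.begin(), m_f.end()),
      _["positions"] = NumericVector(pos.begin(), pos.end()),
      _["velocities"] = NumericVector(vel.begin(), vel.end()),
      _["pheromone"] = NumericVector(pher.begin(), pher.end()),
      _["termination"] = termination,
      _["steps"] = steps_done);
  if (record_trajectory) {
    out["traj_positions"] = traj_pos;
    out["traj_velocities"] = traj_vel;
    out["traj_pheromone"] = traj_pher;
  }
  return out;
}
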