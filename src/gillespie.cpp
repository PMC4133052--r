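// Exact event-driven (Gillespie) simulation of a metapopulation crossing a
// fitness valley or plateau.
//
// State: counts n[g][d] of individuals with genotype g in {0,1,2} in deme d.
// Events and rates (carrying-capacity scheme):
//   division  : each individual of genotype g in deme d at rate
//               f[g] * max(0, 1 - N_d / K_d)   (logistic growth);
//               the offspring mutates g -> g+1 with probability mu (g < 2)
//   death     : each individual at rate g_death
//   migration : total rate m * N_total / migration_factor (all-pairs) or the
//               constant m_total (hub-and-spoke); an event picks two demes,
//               one uniform individual from each, and swaps them
// Fixed-N scheme (validation): per-deme Moran replacement events at rate
// N_d * g_death -- divider chosen proportional to fitness, a uniformly
// chosen individual removed -- with identical mutation/migration semantics.
//
// Waiting times are exponential in the total rate; the event is chosen with
// probability proportional to its rate. Aggregate division rates per deme
// are maintained incrementally and refreshed periodically to cancel
// floating-point drift.

#include <Rcpp.h>
#include "rng.h"
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SimState {
  int D;
  std::vector<long> n0, n1, n2;   // per-deme genotype counts
  std::vector<long> Nd;           // per-deme sizes
  std::vector<double> Kd;         // carrying capacities (scheme 0)
  std::vector<double> phi;        // sum_i n_i f_i per deme
  std::vector<double> B;          // per-deme division rate (scheme 0)
  double f0, f1, f2;
  long Ntot, n2tot;
  double sumB;

  long cnt(int g, int d) const {
    return g == 0 ? n0[d] : (g == 1 ? n1[d] : n2[d]);
  }
  void add(int g, int d, long delta) {
    if (g == 0) n0[d] += delta; else if (g == 1) n1[d] += delta;
    else { n2[d] += delta; n2tot += delta; }
    Nd[d] += delta;
    Ntot += delta;
    phi[d] += delta * (g == 0 ? f0 : (g == 1 ? f1 : f2));
  }
  // swap genotypes only (migration): sizes unchanged
  void swap_genotype(int d, int g_out, int g_in) {
    if (g_out == 0) n0[d]--; else if (g_out == 1) n1[d]--;
    else { n2[d]--; n2tot--; }
    if (g_in == 0) n0[d]++; else if (g_in == 1) n1[d]++;
    else { n2[d]++; n2tot++; }
    phi[d] += (g_in == 0 ? f0 : (g_in == 1 ? f1 : f2)) -
              (g_out == 0 ? f0 : (g_out == 1 ? f1 : f2));
  }
  double deme_B(int d) const {
    double lic = 1.0 - (double)Nd[d] / Kd[d];
    if (lic < 0) lic = 0;
    return phi[d] * lic;
  }
  void refresh_B(int d) {
    sumB += deme_B(d) - B[d];
    B[d] = deme_B(d);
  }
  void full_refresh() {
    sumB = 0;
    for (int d = 0; d < D; ++d) {
      phi[d] = n0[d] * f0 + n1[d] * f1 + n2[d] * f2;
      B[d] = deme_B(d);
      sumB += B[d];
    }
  }
};

// pick index proportional to weights w (total known); linear scan
inline int pick_weighted(const std::vector<double>& w, double total,
                         FastRng& rng) {
  double u = rng.runif() * total;
  int last = (int)w.size() - 1;
  for (int i = 0; i < last; ++i) {
    u -= w[i];
    if (u <= 0) return i;
  }
  return last;
}

inline int pick_deme_by_size(const SimState& st, FastRng& rng) {
  double u = rng.runif() * (double)st.Ntot;
  int last = st.D - 1;
  for (int d = 0; d < last; ++d) {
    u -= (double)st.Nd[d];
    if (u <= 0) return d;
  }
  return last;
}

// genotype of a uniformly chosen individual in deme d
inline int pick_genotype_uniform(const SimState& st, int d,
                                 FastRng& rng) {
  double u = rng.runif() * (double)st.Nd[d];
  u -= (double)st.n0[d];
  if (u <= 0) return 0;
  u -= (double)st.n1[d];
  if (u <= 0) return 1;
  return 2;
}

// genotype of a fitness-weighted chosen individual in deme d
inline int pick_genotype_fitness(const SimState& st, int d,
                                 FastRng& rng) {
  double u = rng.runif() * st.phi[d];
  u -= st.n0[d] * st.f0;
  if (u <= 0) return 0;
  u -= st.n1[d] * st.f1;
  if (u <= 0) return 1;
  return 2;
}

} // namespace

// [[Rcpp::export]]
List sim_crossing_cpp(IntegerMatrix init,        // 3 x D genotype counts
                      NumericVector K,           // carrying capacity per deme
                      NumericVector fitness,     // f0, f1, f2
                      double g_death, double mu, double m,
                      double migration_factor,
                      int topology,              // 0 all-pairs, 1 hub (deme 0)
                      double m_total,            // hub total migration rate
                      int scheme,                // 0 carrying-capacity, 1 fixed-N
                      double t_max,
                      bool stop_when_monomorphic = false,
                      bool stop_at_first_fix = false,
                      double max_events = 2e10) {
  const int D = init.ncol();
  if (init.nrow() != 3) stop("init must be a 3 x D matrix");
  SimState st;
  st.D = D;
  st.f0 = fitness[0]; st.f1 = fitness[1]; st.f2 = fitness[2];
  st.n0.resize(D); st.n1.resize(D); st.n2.resize(D);
  st.Nd.resize(D); st.Kd.resize(D); st.phi.resize(D); st.B.resize(D);
  st.Ntot = 0; st.n2tot = 0;
  for (int d = 0; d < D; ++d) {
    st.n0[d] = init(0, d); st.n1[d] = init(1, d); st.n2[d] = init(2, d);
    st.Nd[d] = st.n0[d] + st.n1[d] + st.n2[d];
    st.Kd[d] = K[(K.size() == 1) ? 0 : d];
    st.Ntot += st.Nd[d];
    st.n2tot += st.n2[d];
  }
  st.full_refresh();

  RNGScope rng;
  FastRng frng;
  double t = 0.0;
  double crossing_time = NA_REAL, first_fix_time = NA_REAL;
  bool have_first_fix = false;
  double n_div = 0, n_death = 0, n_mut = 0, n_mig = 0, n_noop = 0;
  std::string status = "censored";
  int absorbed_genotype = -1;
  double events = 0;
  long refresh_counter = 0;

  // a deme that already contains only genotype 2 at t = 0
  for (int d = 0; d < D && !have_first_fix; ++d) {
    if (st.Nd[d] > 0 && st.n2[d] == st.Nd[d]) {
      have_first_fix = true;
      first_fix_time = 0.0;
    }
  }
  if (st.Ntot > 0 && st.n2tot == st.Ntot) {
    status = "crossed";
    crossing_time = 0.0;
  }

  while (status == "censored") {
    if (st.Ntot == 0) { status = "degenerate"; break; }
    double mig_rate = (topology == 0)
      ? m * (double)st.Ntot / migration_factor
      : m_total;
    double birth_block = (scheme == 0) ? st.sumB : g_death * (double)st.Ntot;
    double death_block = (scheme == 0) ? g_death * (double)st.Ntot : 0.0;
    double R = birth_block + death_block + mig_rate;
    if (R <= 0) { status = "degenerate"; break; }

    t += frng.rexp() / R;
    if (t > t_max) { status = "censored"; break; }

    double u = frng.runif() * R;
    int touched1 = -1, touched2 = -1;
    if (u < birth_block) {
      if (scheme == 0) {
        // division in deme d, genotype by n * f within the deme
        int d = pick_weighted(st.B, st.sumB, frng);
        int gpar = pick_genotype_fitness(st, d, frng);
        int goff = gpar;
        if (gpar < 2 && mu > 0 && frng.runif() < mu) { goff = gpar + 1; n_mut += 1; }
        st.add(goff, d, 1);
        st.refresh_B(d);
        n_div += 1;
        touched1 = d;
      } else {
        // fixed-N Moran replacement: divider by fitness, victim uniform
        int d = pick_deme_by_size(st, frng);
        int gpar = pick_genotype_fitness(st, d, frng);
        int goff = gpar;
        if (gpar < 2 && mu > 0 && frng.runif() < mu) { goff = gpar + 1; n_mut += 1; }
        int gvic = pick_genotype_uniform(st, d, frng);
        if (goff != gvic) st.swap_genotype(d, gvic, goff);
        n_div += 1;
        touched1 = d;
      }
    } else if (u < birth_block + death_block) {
      int d = pick_deme_by_size(st, frng);
      int gd = pick_genotype_uniform(st, d, frng);
      st.add(gd, d, -1);
      st.refresh_B(d);
      n_death += 1;
      touched1 = d;
    } else {
      // migration: swap one uniform individual between two demes
      int d1, d2;
      if (topology == 0) {
        d1 = (int)(frng.runif() * D); if (d1 >= D) d1 = D - 1;
        d2 = (int)(frng.runif() * (D - 1)); if (d2 >= D - 1) d2 = D - 2;
        if (d2 >= d1) d2++;
      } else {
        d1 = 0;
        d2 = 1 + (int)(frng.runif() * (D - 1)); if (d2 >= D) d2 = D - 1;
      }
      n_mig += 1;
      if (st.Nd[d1] == 0 || st.Nd[d2] == 0) {
        n_noop += 1;
      } else {
        int ga = pick_genotype_uniform(st, d1, frng);
        int gb = pick_genotype_uniform(st, d2, frng);
        if (ga != gb) {
          st.swap_genotype(d1, ga, gb);
          st.swap_genotype(d2, gb, ga);
          if (scheme == 0) { st.refresh_B(d1); st.refresh_B(d2); }
        } else {
          n_noop += 1;
        }
      }
      touched1 = d1; touched2 = d2;
    }

    if (!have_first_fix) {
      for (int pass = 0; pass < 2; ++pass) {
        int d = pass == 0 ? touched1 : touched2;
        if (d >= 0 && st.Nd[d] > 0 && st.n2[d] == st.Nd[d]) {
          have_first_fix = true;
          first_fix_time = t;
          break;
        }
      }
    }
    if (st.Ntot > 0 && st.n2tot == st.Ntot) {
      status = "crossed";
      crossing_time = t;
      break;
    }
    if (stop_at_first_fix && have_first_fix) {
      status = "first_fix";
      break;
    }
    if (stop_when_monomorphic && mu == 0 && st.n2tot == 0) {
      long tot0 = 0, tot1 = 0;
      for (int d = 0; d < D; ++d) { tot0 += st.n0[d]; tot1 += st.n1[d]; }
      if (tot0 == st.Ntot || tot1 == st.Ntot) {
        status = "absorbed";
        absorbed_genotype = (tot0 == st.Ntot) ? 0 : 1;
        break;
      }
    }

    events += 1;
    if (events >= max_events) { status = "event_cap"; break; }
    if (++refresh_counter >= (1 << 20)) {
      refresh_counter = 0;
      st.full_refresh();
    }
  }

  IntegerMatrix final_counts(3, D);
  for (int d = 0; d < D; ++d) {
    final_counts(0, d) = (int)st.n0[d];
    final_counts(1, d) = (int)st.n1[d];
    final_counts(2, d) = (int)st.n2[d];
  }
  return List::create(
    _["status"] = status,
    _["crossing_time"] = crossing_time,
    _["first_deme_fix_time"] = first_fix_time,
    _["t_end"] = t,
    _["absorbed_genotype"] = absorbed_genotype,
    _["n_divisions"] = n_div, _["n_deaths"] = n_death,
    _["n_mutations"] = n_mut, _["n_migrations"] = n_mig,
    _["n_noop_migrations"] = n_noop,
    _["n_events"] = events,
    _["final_counts"] = final_counts
  );
}

// Time-averaged occupancy of a metapopulation with no mutation, for
// validating the logistic steady state N ~= K (1 - g / fbar).
// [[Rcpp::export]]
List sim_occupancy_cpp(IntegerMatrix init, NumericVector K,
                       NumericVector fitness, double g_death,
                       double t_total, double t_burnin) {
  const int D = init.ncol();
  SimState st;
  st.D = D;
  st.f0 = fitness[0]; st.f1 = fitness[1]; st.f2 = fitness[2];
  st.n0.resize(D); st.n1.resize(D); st.n2.resize(D);
  st.Nd.resize(D); st.Kd.resize(D); st.phi.resize(D); st.B.resize(D);
  st.Ntot = 0; st.n2tot = 0;
  for (int d = 0; d < D; ++d) {
    st.n0[d] = init(0, d); st.n1[d] = init(1, d); st.n2[d] = init(2, d);
    st.Nd[d] = st.n0[d] + st.n1[d] + st.n2[d];
    st.Kd[d] = K[(K.size() == 1) ? 0 : d];
    st.Ntot += st.Nd[d];
  }
  st.full_refresh();
  RNGScope rng;
  FastRng frng;
  double t = 0.0, integral = 0.0, integral_sq = 0.0;
  long refresh_counter = 0;
  while (t < t_total && st.Ntot > 0) {
    double R = st.sumB + g_death * (double)st.Ntot;
    if (R <= 0) break;
    double dt = frng.rexp() / R;
    double t_new = t + dt;
    if (t >= t_burnin) {
      double w = std::min(t_new, t_total) - t;
      integral += w * (double)st.Ntot;
      integral_sq += w * (double)st.Ntot * (double)st.Ntot;
    } else if (t_new > t_burnin) {
      double w = std::min(t_new, t_total) - t_burnin;
      integral += w * (double)st.Ntot;
      integral_sq += w * (double)st.Ntot * (double)st.Ntot;
    }
    t = t_new;
    if (t > t_total) break;
    double u = frng.runif() * R;
    if (u < st.sumB) {
      int d = pick_weighted(st.B, st.sumB, frng);
      int gg = pick_genotype_fitness(st, d, frng);
      st.add(gg, d, 1);
      st.refresh_B(d);
    } else {
      int d = pick_deme_by_size(st, frng);
      int gg = pick_genotype_uniform(st, d, frng);
      st.add(gg, d, -1);
      st.refresh_B(d);
    }
    if (++refresh_counter >= (1 << 20)) { refresh_counter = 0; st.full_refresh(); }
  }
  double span = t_total - t_burnin;
  return List::create(
    _["mean_total_size"] = integral / span,
    _["mean_square_total_size"] = integral_sq / span,
    _["t_end"] = t
  );
}
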