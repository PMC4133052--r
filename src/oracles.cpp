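// Small, self-contained Monte-Carlo routines used as independent oracles
// for the closed-form theory: a Moran fixation experiment, a random walk on
// the deme-exchange birth-death chain, and a branching-process experiment
// for the tunneling success probability. None of these share code with the
// analytic implementations they validate.

#include <Rcpp.h>
#include "rng.h"
#include <cmath>
using namespace Rcpp;

// Fraction of trials in which the lineage of a single mutant (fitness
// f_mut) fixes in a Moran population of size N of residents (fitness
// f_res). Simulates the embedded jump chain of the Moran process: given
// that the mutant count changes, it increases with probability
// f_mut / (f_mut + f_res).
// [[Rcpp::export]]
List moran_fixation_mc(int N, double f_res, double f_mut, int n_trials) {
  if (N < 2) stop("N must be >= 2");
  RNGScope rng;
  FastRng frng;
  const double p_up = f_mut / (f_mut + f_res);
  long fixed = 0;
  for (int tr = 0; tr < n_trials; ++tr) {
    int j = 1;
    while (j > 0 && j < N) {
      j += (frng.runif() < p_up) ? 1 : -1;
    }
    if (j == N) fixed++;
  }
  double p = (double)fixed / n_trials;
  return List::create(
    _["p_fix"] = p,
    _["se"] = std::sqrt(p * (1 - p) / n_trials),
    _["n_trials"] = n_trials
  );
}

// Random walks on the birth-death chain over the number k of mutant-fixed
// demes, counting migration events (chain steps, self-loops included)
// until absorption at 0 or D. Self-loop runs are drawn as exact geometric
// variates rather than stepped through.
// [[Rcpp::export]]
List chain_walk_mc(int D, double rho_up, double rho_down, int start_k,
                   int n_walks) {
  if (D < 2 || start_k < 0 || start_k > D) stop("bad chain geometry");
  RNGScope rng;
  FastRng frng;
  const double up_unit = rho_up * (1 - rho_down);
  const double down_unit = rho_down * (1 - rho_up);
  const double p_up_given_move = up_unit / (up_unit + down_unit);
  const double pair_norm = (double)D * (D - 1) / 2.0;
  long n_top = 0;
  double sum_top = 0, sumsq_top = 0, sum_bot = 0, sumsq_bot = 0;
  for (int w = 0; w < n_walks; ++w) {
    int k = start_k;
    double steps = 0;
    while (k > 0 && k < D) {
      double q_k = (double)k * (D - k) / pair_norm;
      double p_leave = q_k * (up_unit + down_unit);
      // geometric number of events until the state changes
      double u = frng.runif();
      double run = std::floor(std::log(u) / std::log1p(-p_leave)) + 1.0;
      steps += run;
      k += (frng.runif() < p_up_given_move) ? 1 : -1;
    }
    if (k == D) {
      n_top++; sum_top += steps; sumsq_top += steps * steps;
    } else {
      sum_bot += steps; sumsq_bot += steps * steps;
    }
  }
  long n_bot = n_walks - n_top;
  return List::create(
    _["pi_top"] = (double)n_top / n_walks,
    _["n_top"] = (double)n_top, _["n_bottom"] = (double)n_bot,
    _["mean_steps_top"] = n_top ? sum_top / n_top : NA_REAL,
    _["mean_steps_bottom"] = n_bot ? sum_bot / n_bot : NA_REAL,
    _["sd_steps_top"] = n_top > 1
      ? std::sqrt((sumsq_top - sum_top * sum_top / n_top) / (n_top - 1))
      : NA_REAL,
    _["sd_steps_bottom"] = n_bot > 1
      ? std::sqrt((sumsq_bot - sum_bot * sum_bot / n_bot) / (n_bot - 1))
      : NA_REAL
  );
}

// Branching-process experiment for the probability that a single
// intermediate ('1') mutant is "successful": its lineage produces a final
// ('2') mutant that establishes, before the lineage dies out. Each '1'
// individual divides at rate proportional to 1 - delta and dies at rate 1
// (the resident-background turnover); each division's offspring mutates
// with probability mu, and a '2' mutant establishes with probability
// s_est. The lineage size is capped at size_cap (success is then forced:
// such lineages have effectively escaped drift loss -- only reachable for
// delta <= 0).
// [[Rcpp::export]]
List lineage_success_mc(double delta, double mu, double s_est,
                        int n_lineages, int size_cap = 1000000) {
  RNGScope rng;
  FastRng frng;
  const double birth_prob = (1.0 - delta) / (2.0 - delta);
  const double q = mu * s_est;   // success probability per division
  long success = 0;
  for (int l = 0; l < n_lineages; ++l) {
    long n = 1;
    while (n > 0) {
      if (frng.runif() < birth_prob) {
        if (q > 0 && frng.runif() < q) { success++; break; }
        if (++n >= size_cap) { success++; break; }
      } else {
        --n;
      }
    }
  }
  double p = (double)success / n_lineages;
  return List::create(
    _["p_success"] = p,
    _["se"] = std::sqrt(p * (1 - p) / n_lineages),
    _["n_lineages"] = n_lineages
  );
}
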