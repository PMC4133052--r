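# Monte-Carlo validation oracles. These deliberately share no code with
# the closed forms they are used to check.

#' Monte-Carlo Moran fixation experiment
#'
#' Simulates the embedded jump chain of the Moran process (`n_trials`
#' independent single-mutant invasions) and reports the fixation fraction
#' with its binomial standard error. Used as an independent check of
#' [fixation_probability()].
#'
#' @param N Population size.
#' @param f_resident,f_mutant Fitnesses.
#' @param n_trials Number of invasion trials.
#' @param seed Optional seed.
#' @return List: `p_fix`, `se`, `n_trials`.
#' @export
moran_fixation_oracle <- function(N, f_resident, f_mutant, n_trials,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  moran_fixation_mc(as.integer(N), f_resident, f_mutant,
                    as.integer(n_trials))
}

#' Monte-Carlo walks on the deme-exchange chain
#'
#' Simulates random walks on the birth-death chain of [build_chain()]
#' (self-loop runs drawn as exact geometric variates) and reports the
#' absorption fractions and conditional mean step counts. Used as an
#' independent check of [absorption_stats()].
#'
#' @param D,rho_up,rho_down Chain parameters as in [build_chain()].
#' @param start_k Starting state.
#' @param n_walks Number of walks.
#' @param seed Optional seed.
#' @return List with `pi_top`, `mean_steps_top`, `mean_steps_bottom`,
#'   their standard deviations and the walk counts per side.
#' @export
chain_walk_oracle <- function(D, rho_up, rho_down, start_k, n_walks,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chain_walk_mc(as.integer(D), rho_up, rho_down, as.integer(start_k),
                as.integer(n_walks))
}

#' Monte-Carlo tunneling-lineage experiment
#'
#' Simulates branching lineages founded by a single intermediate mutant
#' (birth rate proportional to `1 - delta`, death rate 1, forward mutation
#' with probability `mu` per division, establishment of the final genotype
#' with probability `s_est`) and reports the fraction of "successful"
#' lineages. Used as an independent check of
#' [tunneling_success_probability()]; note the closed form is itself a
#' small-`mu*s_est` approximation, accurate to `O(sqrt(mu * s_est))`
#' relative error.
#'
#' @param delta Intermediate fitness deficit.
#' @param mu Mutation probability per division.
#' @param s_est Establishment probability of the final genotype.
#' @param n_lineages Number of founder lineages.
#' @param seed Optional seed.
#' @return List: `p_success`, `se`, `n_lineages`.
#' @export
lineage_success_oracle <- function(delta, mu, s_est, n_lineages,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lineage_success_mc(delta, mu, s_est, as.integer(n_lineages))
}

#' Time-averaged occupancy of a mutation-free metapopulation
#'
#' Runs the carrying-capacity Gillespie dynamics with `mu = 0` and returns
#' the time-averaged total population size after a burn-in, for checking
#' the logistic steady state `N = K (1 - g / fbar)` per deme.
#'
#' @param deme A [deme_spec()].
#' @param D Number of demes.
#' @param t_total Total simulated time.
#' @param t_burnin Burn-in discarded from the average.
#' @param seed Optional seed.
#' @return List: `mean_total_size`, `mean_square_total_size`, `t_end`.
#' @export
occupancy_simulation <- function(deme, D, t_total, t_burnin = 0,
                                 seed = NULL) {
  stopifnot(inherits(deme, "deme_spec"))
  if (!is.null(seed)) set.seed(seed)
  init <- rbind(rep(deme$N, D), 0L, 0L)
  sim_occupancy_cpp(matrix(as.integer(init), nrow = 3),
                    rep(as.numeric(deme$K), D), c(1, 1, 1), deme$g,
                    t_total, t_burnin)
}
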