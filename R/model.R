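#' Define a two-step fitness landscape
#'
#' The minimal rugged landscape: three successive genotypes `0 -> 1 -> 2`
#' with fitnesses `f0 = 1`, `f1 = 1 - delta` and `f2 = 1 + s`. A positive
#' `delta` is a fitness valley (deleterious intermediate), `delta = 0` a
#' plateau (neutral intermediate), and a small negative `delta` a weakly
#' beneficial intermediate. Each division produces one offspring that
#' acquires the next forward mutation with probability `mu`; there are no
#' back mutations and genotype `2` does not mutate.
#'
#' @param delta Fitness deficit of the intermediate genotype (dimensionless,
#'   signed). Must satisfy `delta < s` and `1 - delta > 0`.
#' @param s Fitness advantage of the final genotype (dimensionless, `> 0`).
#' @param mu Mutation probability per division, in `(0, 1)`.
#'
#' @return An object of class `fitness_landscape` with fields `delta`, `s`,
#'   `mu` and the derived fitness vector `f = c(f0, f1, f2)`.
#' @examples
#' fitness_landscape(delta = 0.05, s = 0.1, mu = 1e-5)
#' @export
fitness_landscape <- function(delta, s, mu) {
  stop_invalid(is.numeric(delta) && length(delta) == 1L && is.finite(delta),
               "delta", "must be a finite number")
  stop_invalid(is.numeric(s) && length(s) == 1L && is.finite(s) && s > 0,
               "s", "must be a positive number")
  stop_invalid(is.numeric(mu) && length(mu) == 1L && mu >= 0 && mu < 1,
               "mu", "must lie in [0, 1)")
  stop_invalid(delta < s, "delta", "must be smaller than s (genotype '2' is the fittest)")
  stop_invalid(1 - delta > 0, "delta", "implies non-positive intermediate fitness")
  if (abs(delta) > 0.3) {
    warning("|delta| = ", abs(delta),
            " is large; the weak-selection approximations assume |delta| << 1",
            call. = FALSE)
  }
  structure(
    list(delta = delta, s = s, mu = mu, f = c(1, 1 - delta, 1 + s)),
    class = "fitness_landscape"
  )
}

#' Define a deme (subpopulation)
#'
#' A deme is characterised by its carrying capacity `K` (used by the
#' logistic-growth simulator, in which each individual divides at rate
#' `f_i (1 - N_d / K)` and dies at rate `g`) and by the analytic deme size
#' `N` used by all closed-form theory. At steady state the division rate
#' averaged over a deme balances the death rate, so the occupancy
#' fluctuates around `N = K (1 - g / fbar)`; by default `N` is derived from
#' `K` with mean fitness `fbar = 1`.
#'
#' @param K Carrying capacity (individuals, `>= 2`).
#' @param g Death rate per individual per unit time (`> 0`); also the
#'   per-capita turnover rate at equilibrium. Default `0.1`.
#' @param N Analytic deme size. If `NULL` (default), derived via
#'   [equilibrium_deme_size()].
#'
#' @return An object of class `deme_spec` with fields `K`, `g`, `N`.
#' @examples
#' deme_spec(K = 1000, g = 0.1) # N = 900
#' @export
deme_spec <- function(K, g = 0.1, N = NULL) {
  stop_invalid(is.numeric(K) && length(K) == 1L && K >= 2, "K", "must be >= 2")
  stop_invalid(is.numeric(g) && length(g) == 1L && g > 0, "g", "must be > 0")
  if (is.null(N)) {
    N <- equilibrium_deme_size(K, g)
  }
  stop_invalid(is.numeric(N) && length(N) == 1L && N >= 2, "N", "must be >= 2")
  structure(list(K = K, g = g, N = as.integer(round(N))), class = "deme_spec")
}

#' Equilibrium deme size under logistic birth-death dynamics
#'
#' With logistic division rate `fbar (1 - N/K)` per individual and constant
#' death rate `g`, the population settles where division balances death:
#' `N = K (1 - g / fbar)`.
#'
#' @param K Carrying capacity (`>= 2`).
#' @param g Death rate per individual per unit time.
#' @param mean_fitness Mean fitness `fbar` of the deme (default 1, the
#'   ancestral genotype).
#' @return Integer equilibrium size (rounded, at least 2).
#' @examples
#' equilibrium_deme_size(1000, 0.1) # 900
#' @export
equilibrium_deme_size <- function(K, g, mean_fitness = 1) {
  stop_invalid(is.numeric(K) && length(K) == 1L && K >= 2, "K", "must be >= 2")
  stop_invalid(is.numeric(g) && length(g) == 1L && g > 0, "g", "must be > 0")
  stop_invalid(g < mean_fitness, "g",
               "must be smaller than the mean fitness (population cannot persist)")
  N <- as.integer(round(K * (1 - g / mean_fitness)))
  max(N, 2L)
}

#' Define a metapopulation
#'
#' `D` identical demes coupled by migration. Under the `"all-pairs"` island
#' topology every exchange picks two distinct demes uniformly at random and
#' swaps one uniformly chosen individual from each; each individual changes
#' deme at rate `m`, so migration events occur at total rate
#' `m * N_total / migration_factor` with `migration_factor = 2` (each event
#' relocates two individuals). Under `"hub-and-spoke"` one large population
#' exchanges migrants with `C` satellite islands at total event rate
#' `m_total_island`, the island being chosen uniformly at each event.
#'
#' @param D Number of demes (`>= 1`).
#' @param m Migration rate per individual per unit time (`>= 0`). Must be
#'   much smaller than the turnover rate `g` for the theory to apply.
#' @param topology `"all-pairs"` (default) or `"hub-and-spoke"`.
#' @param N_large,C,N_island,m_total_island Hub-and-spoke fields: size of the
#'   large population, number of satellite islands, island size, and total
#'   migration-event rate.
#' @param migration_factor Convention constant relating the per-individual
#'   rate `m` to the total event rate `M_tot = m * N_total / migration_factor`.
#'   Default 2.
#'
#' @return An object of class `metapop_spec`.
#' @export
metapop_spec <- function(D, m, topology = c("all-pairs", "hub-and-spoke"),
                         N_large = NULL, C = NULL, N_island = NULL,
                         m_total_island = NULL, migration_factor = 2) {
  topology <- match.arg(topology)
  stop_invalid(is.numeric(D) && length(D) == 1L && D >= 1 && D == round(D),
               "D", "must be an integer >= 1")
  stop_invalid(is.numeric(m) && length(m) == 1L && m >= 0, "m", "must be >= 0")
  stop_invalid(migration_factor > 0, "migration_factor", "must be > 0")
  if (topology == "hub-and-spoke") {
    stop_invalid(!is.null(N_large) && !is.null(C) && !is.null(N_island) &&
                   !is.null(m_total_island),
                 "topology",
                 "hub-and-spoke requires N_large, C, N_island and m_total_island")
    stop_invalid(N_island < N_large, "N_island", "must be smaller than N_large")
    stop_invalid(C >= 1 && C == round(C), "C", "must be an integer >= 1")
    stop_invalid(m_total_island >= 0, "m_total_island", "must be >= 0")
  }
  structure(
    list(D = as.integer(D), m = m, topology = topology,
         N_large = N_large, C = if (!is.null(C)) as.integer(C) else NULL,
         N_island = N_island, m_total_island = m_total_island,
         migration_factor = migration_factor),
    class = "metapop_spec"
  )
}

#' Validate a model configuration and compute regime flags
#'
#' Checks hard constraints (raising an error with the offending field) and
#' recomputes the soft validity flags from scratch:
#' \describe{
#'   \item{effective_neutrality}{`N |delta| < 1`: drift dominates selection on
#'     the intermediate inside a deme, so plateau results apply.}
#'   \item{low_migration}{`m / g` below `tol_migration`: demes resolve each
#'     migrant's fate (fixation or loss) before the next exchange.}
#'   \item{mutation_supply_ok}{`N mu` below `tol_mutation_supply`: no
#'     competition between concurrent mutant lineages (excludes the
#'     semi-deterministic, large mutation-supply regime).}
#' }
#'
#' @param landscape A [fitness_landscape()].
#' @param deme A [deme_spec()].
#' @param metapop A [metapop_spec()].
#' @param tol_neutrality,tol_migration,tol_mutation_supply Thresholds for the
#'   three flags (defaults 1, 0.1 and 0.1).
#' @return A list of class `validity_flags` with the three booleans plus the
#'   regime label of a single deme and of the pooled non-subdivided
#'   population (`"sequential"` or `"tunneling"`).
#' @export
validate_model <- function(landscape, deme, metapop,
                           tol_neutrality = 1, tol_migration = 0.1,
                           tol_mutation_supply = 0.1) {
  stopifnot(inherits(landscape, "fitness_landscape"),
            inherits(deme, "deme_spec"),
            inherits(metapop, "metapop_spec"))
  stop_invalid(landscape$mu > 0, "mu", "must be > 0 for crossing to be possible")
  N <- deme$N
  flags <- list(
    effective_neutrality = N * abs(landscape$delta) < tol_neutrality,
    low_migration = metapop$m / deme$g < tol_migration,
    mutation_supply_ok = N * landscape$mu < tol_mutation_supply,
    regime_deme = classify_regime(landscape, N, deme$g)$regime,
    regime_nonsubdivided =
      classify_regime(landscape, N * metapop$D, deme$g)$regime
  )
  class(flags) <- "validity_flags"
  flags
}

# internal: uniform error type carrying the offending field name
stop_invalid <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(structure(
      class = c("invalid_parameter", "error", "condition"),
      list(message = sprintf("invalid parameter '%s': %s", field, msg),
           call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

#' @export
print.fitness_landscape <- function(x, ...) {
  kind <- if (x$delta > 0) "valley" else if (x$delta == 0) "plateau"
          else "weakly beneficial intermediate"
  cat(sprintf("fitness landscape (%s): delta = %g, s = %g, mu = %g\n",
              kind, x$delta, x$s, x$mu))
  cat(sprintf("  fitnesses f0, f1, f2 = %g, %g, %g\n", x$f[1], x$f[2], x$f[3]))
  invisible(x)
}

#' @export
print.deme_spec <- function(x, ...) {
  cat(sprintf("deme: K = %g, g = %g, equilibrium N = %d\n", x$K, x$g, x$N))
  invisible(x)
}

#' @export
print.metapop_spec <- function(x, ...) {
  if (x$topology == "all-pairs") {
    cat(sprintf("metapopulation: D = %d demes, m = %g (all-pairs exchange)\n",
                x$D, x$m))
  } else {
    cat(sprintf(
      "metapopulation: hub (N = %g) + %d islands (N = %g), m_total = %g\n",
      x$N_large, x$C, x$N_island, x$m_total_island))
  }
  invisible(x)
}
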