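#' Birth-death Markov chain over the number of mutant-fixed demes
#'
#' Between mutation events, the number `k` of demes fixed for a mutant
#' genotype evolves only through migration. Each migration event exchanges
#' individuals between two uniformly chosen demes, so it is "relevant"
#' (capable of changing `k`) with probability
#' `q(k) = k (D - k) / choose(D, 2)`. A relevant event increases `k` with
#' probability `rho_up (1 - rho_down)` (the mutant migrant fixes in the
#' wild-type deme while the wild-type migrant is lost) and decreases it
#' with probability `rho_down (1 - rho_up)`; otherwise `k` is unchanged.
#' The resulting chain is tri-diagonal with absorbing states `k = 0` and
#' `k = D`, and each chain step is one migration event.
#'
#' @param D Number of demes (`>= 2`).
#' @param rho_up Probability that a mutant migrant fixes in a wild-type deme.
#' @param rho_down Probability that a wild-type migrant fixes in a mutant deme.
#' @return An object of class `birth_death_chain`: `D`, `rho_up`, `rho_down`,
#'   the relevance probabilities `q` (indexed `k = 0..D`) and the full
#'   `(D+1) x (D+1)` transition matrix `P`.
#' @export
build_chain <- function(D, rho_up, rho_down) {
  stop_invalid(D >= 2 && D == round(D), "D", "must be an integer >= 2")
  stop_invalid(rho_up >= 0 && rho_up < 1, "rho_up", "must lie in [0, 1)")
  stop_invalid(rho_down >= 0 && rho_down < 1, "rho_down", "must lie in [0, 1)")
  stop_invalid(rho_up > 0 || rho_down > 0, "rho_up",
               "rho_up and rho_down cannot both be zero")
  # fixation probabilities that underflow to double zero (e.g. a strongly
  # deleterious migrant in a huge deme) are floored at the smallest normal
  rho_up <- max(rho_up, 2.3e-308)
  rho_down <- max(rho_down, 2.3e-308)
  k <- 0:D
  q <- k * (D - k) / (D * (D - 1) / 2)
  up_unit <- rho_up * (1 - rho_down)
  down_unit <- rho_down * (1 - rho_up)
  P <- matrix(0, D + 1, D + 1)
  for (i in seq_len(D - 1)) {              # interior states k = 1..D-1
    kk <- i + 1L                           # matrix row of state k = i
    P[kk, kk + 1L] <- q[kk] * up_unit
    P[kk, kk - 1L] <- q[kk] * down_unit
    P[kk, kk] <- 1 - P[kk, kk + 1L] - P[kk, kk - 1L]
  }
  P[1L, 1L] <- 1
  P[D + 1L, D + 1L] <- 1
  structure(list(D = D, rho_up = rho_up, rho_down = rho_down, q = q, P = P,
                 up_unit = up_unit, down_unit = down_unit),
            class = "birth_death_chain")
}

# log of sum_{i=a}^{b} exp(i * logr)  (geometric sum in log space, a <= b)
log_geom_sum <- function(logr, a, b) {
  i <- a:b
  m <- max(i * logr)
  m + log(sum(exp(i * logr - m)))
}

#' Absorption statistics of the deme-exchange chain
#'
#' Computes, for a [build_chain()] object, the probability of absorbing at
#' `k = D` (all demes mutant) versus `k = 0` (mutant lost), and the expected
#' number of chain steps -- migration events -- to absorption, conditional
#' on each outcome. Two independent routes are used: the closed-form
#' expressions built from the cumulative products
#' `gamma_j = (rho_down (1-rho_up) / (rho_up (1-rho_down)))^j` (evaluated in
#' log space, so deep valleys with ratios spanning hundreds of orders of
#' magnitude do not overflow), and a direct solve of the tri-diagonal linear
#' systems. The two must agree to `tol` relative error; disagreement raises
#' a `numerical_instability` error.
#'
#' @param chain A [build_chain()] object.
#' @param start_k Starting number of mutant demes (`0 <= start_k <= D`).
#' @param tol Relative agreement required between the two routes.
#' @return List of class `absorption_stats`: `pi_top` / `pi_bottom`
#'   (absorption probabilities from `start_k`), `n_steps_top` /
#'   `n_steps_bottom` (conditional expected migration events; `NA` when the
#'   corresponding absorption has probability 0), `n_steps_unconditional`,
#'   and the full per-state vectors `pi_top_all` etc. (indexed `k = 0..D`).
#' @export
absorption_stats <- function(chain, start_k, tol = 1e-10) {
  stopifnot(inherits(chain, "birth_death_chain"))
  D <- chain$D
  stop_invalid(start_k >= 0 && start_k <= D && start_k == round(start_k),
               "start_k", "must be an integer in [0, D]")
  closed <- absorption_closed_form(chain)
  solved <- absorption_linear_solve(chain)
  # cross-validate wherever the dense solve is well-conditioned: absorption
  # probabilities far below ~1e-8 (deep-valley chains) cancel to noise in the
  # dense solve, while the log-space closed form remains exact there
  # the dense solve carries ~1e-15 absolute error on the absorption
  # probabilities, so conditional quantities attached to outcomes rarer
  # than ~1e-4 are outside its reach and only the closed form applies
  pi_ok <- closed$pi_top_all > 1e-4
  masks <- list(pi_top_all = pi_ok,
                steps_top_all = pi_ok,
                steps_bottom_all = closed$pi_bottom_all > 1e-4,
                steps_unconditional_all = rep(TRUE, D + 1))
  for (fld in names(masks)) {
    a <- closed[[fld]]; b <- solved[[fld]]
    ok <- is.finite(a) & is.finite(b) & masks[[fld]] & abs(b) > 0
    if (any(ok) && max(abs(a[ok] - b[ok]) / pmax(abs(b[ok]), 1e-300)) > tol) {
      stop(structure(
        class = c("numerical_instability", "error", "condition"),
        list(message = paste0("absorption_stats: closed form and linear solve ",
                              "disagree beyond tolerance on ", fld),
             call = sys.call())))
    }
  }
  i <- start_k + 1L
  structure(list(
    D = D, start_k = start_k,
    pi_top = closed$pi_top_all[i],
    pi_bottom = closed$pi_bottom_all[i],
    n_steps_top = closed$steps_top_all[i],
    n_steps_bottom = closed$steps_bottom_all[i],
    n_steps_unconditional = closed$steps_unconditional_all[i],
    pi_top_all = closed$pi_top_all,
    pi_bottom_all = closed$pi_bottom_all,
    n_steps_top_all = closed$steps_top_all,
    n_steps_bottom_all = closed$steps_bottom_all,
    n_steps_unconditional_all = closed$steps_unconditional_all
  ), class = "absorption_stats")
}

# closed forms via log-space geometric sums.
# The embedded jump chain (self-loops removed) is a gambler's-ruin walk with
# constant up probability p' = up/(up+down); its Green function
#   G(k, j) = S(0, min(k,j)-1) S(max(k,j), D-1) / (p' gamma_j S(0, D-1))
# gives the expected number of visits to j before absorption; each visit
# lasts 1/(q(j) (up+down)) migration events on average.
absorption_closed_form <- function(chain) {
  D <- chain$D
  logr <- log(chain$down_unit) - log(chain$up_unit)
  logS0 <- log_geom_sum(logr, 0, D - 1)
  log_pi_top <- vapply(0:D, function(k) {
    if (k == 0) -Inf else log_geom_sum(logr, 0, k - 1) - logS0
  }, numeric(1))
  log_pi_bot <- vapply(0:D, function(k) {
    if (k == D) -Inf else log_geom_sum(logr, k, D - 1) - logS0
  }, numeric(1))
  log_pprime <- log(chain$up_unit) - log(chain$up_unit + chain$down_unit)
  log_hold <- -(log(chain$q[2:D]) + log(chain$up_unit + chain$down_unit))
  logG <- function(k, j) { # 1 <= k, j <= D-1
    lo <- min(k, j); hi <- max(k, j)
    log_geom_sum(logr, 0, lo - 1) + log_geom_sum(logr, hi, D - 1) -
      log_pprime - j * logr - logS0
  }
  steps_top <- rep(NA_real_, D + 1)
  steps_bot <- rep(NA_real_, D + 1)
  steps_unc <- rep(0, D + 1)
  for (k in seq_len(D - 1)) {
    lg <- vapply(seq_len(D - 1), function(j) logG(k, j) + log_hold[j],
                 numeric(1))
    steps_unc[k + 1L] <- sum(exp(lg))
    steps_top[k + 1L] <-
      sum(exp(lg + log_pi_top[2:D] - log_pi_top[k + 1L]))
    steps_bot[k + 1L] <-
      sum(exp(lg + log_pi_bot[2:D] - log_pi_bot[k + 1L]))
  }
  steps_top[1L] <- NA_real_; steps_bot[D + 1L] <- NA_real_
  steps_top[D + 1L] <- 0; steps_bot[1L] <- 0
  list(pi_top_all = exp(log_pi_top),
       pi_bottom_all = exp(log_pi_bot),
       steps_top_all = steps_top,
       steps_bottom_all = steps_bot,
       steps_unconditional_all = steps_unc)
}

# dense linear-solve route (independent cross-check). The raw system
# (I - Q) x = b is ill-conditioned when leave rates are tiny (self-loop
# dominated chains), so each transient row is divided by its leave rate
# q(k) (up + down), turning the matrix into the O(1)-conditioned embedded
# jump chain.
absorption_linear_solve <- function(chain) {
  D <- chain$D
  idx <- 2:D                               # transient states k = 1..D-1
  leave <- chain$q[idx] * (chain$up_unit + chain$down_unit)
  up_p <- chain$up_unit / (chain$up_unit + chain$down_unit)
  down_p <- chain$down_unit / (chain$up_unit + chain$down_unit)
  rhs_top <- c(rep(0, D - 2), up_p)
  u <- drop(tridiag_jump_solve(D - 1L, up_p, down_p,
                               cbind(rhs_top)))       # pi_top, transient
  sol <- tridiag_jump_solve(D - 1L, up_p, down_p,
                            cbind(1 / leave, u / leave, (1 - u) / leave))
  ones <- sol[, 1L]                        # unconditional steps
  w_top <- sol[, 2L]                       # E[steps * 1{absorb top}]
  w_bot <- sol[, 3L]
  pi_top_all <- c(0, u, 1)
  steps_top <- c(NA_real_, w_top / u, 0)
  steps_bot <- c(0, w_bot / (1 - u), NA_real_)
  list(pi_top_all = pi_top_all,
       steps_top_all = steps_top,
       steps_bottom_all = steps_bot,
       steps_unconditional_all = c(0, ones, 0))
}

#' Expected migration events for extinction of one mutant deme
#'
#' Starting from one deme fixed for the intermediate genotype `1` amid
#' `D - 1` wild-type demes, `n_e` is the expected number of migration
#' events until the intermediate is wiped out, conditional on that outcome.
#' The chain moves up with the fixation probability `rho01` of a single
#' `1`-migrant among wild types and down with `rho10` of a wild-type
#' migrant among intermediates. The simplified estimate
#' `1 / (q(1) rho10 (1 - rho01))`, valid when `rho01 << rho10` (migration-
#' induced increases negligible), is returned alongside the general
#' chain-based value.
#'
#' @param landscape A [fitness_landscape()].
#' @param N Deme size used for the migrant fixation probabilities.
#' @param D Number of demes (`>= 2`).
#' @param warn Warn when isolated demes are not in the sequential-fixation
#'   regime (the chain picture presumes demes fix the intermediate).
#' @return List: `n_e` (conditional chain value), `n_e_simplified`,
#'   `rho01`, `rho10`, and the underlying `chain` and `stats`.
#' @export
n_extinction <- function(landscape, N, D, warn = TRUE) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  f <- landscape$f
  rho01 <- fixation_probability(f[1], f[2], N)
  rho10 <- fixation_probability(f[2], f[1], N)
  if (warn && landscape$mu > 0 &&
      classify_regime(landscape, N, g = 1)$regime != "sequential") {
    warning("isolated demes of size N = ", N, " are in the tunneling regime; ",
            "the mutant-deme chain presumes sequential fixation", call. = FALSE)
  }
  chain <- build_chain(D, rho_up = rho01, rho_down = rho10)
  stats <- absorption_stats(chain, start_k = 1)
  list(n_e = stats$n_steps_bottom,
       n_e_simplified = 1 / (chain$q[2L] * rho10 * (1 - rho01)),
       rho01 = rho01, rho10 = rho10, chain = chain, stats = stats)
}

#' Expected migration events for spreading of the final mutation
#'
#' Starting from one deme fixed for the beneficial genotype `2` amid
#' `D - 1` wild-type demes, `n_f` is the expected number of migration
#' events until every deme is fixed for `2`, conditional on that outcome.
#' Up moves occur with the fixation probability `rho02` of a `2`-migrant
#' among wild types, down moves with `rho20`. The simplified estimate
#' `sum_k 1 / (q(k) rho02)` neglects down moves (valid for `1/N << s`, so
#' that `rho20` is negligible).
#'
#' @inheritParams n_extinction
#' @return List: `n_f`, `n_f_simplified`, `rho02`, `rho20`, `chain`, `stats`.
#' @export
n_spreading <- function(landscape, N, D, warn = TRUE) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  f <- landscape$f
  rho02 <- fixation_probability(f[1], f[3], N)
  rho20 <- fixation_probability(f[3], f[1], N)
  if (warn && N * landscape$s < 1) {
    warning("N * s = ", N * landscape$s, " < 1: the simplified spreading ",
            "estimate assumes 1/N << s", call. = FALSE)
  }
  chain <- build_chain(D, rho_up = rho02, rho_down = rho20)
  stats <- absorption_stats(chain, start_k = 1)
  k <- seq_len(D - 1)
  q_k <- chain$q[k + 1L]
  list(n_f = stats$n_steps_top,
       n_f_simplified = sum(1 / (q_k * rho02)),
       rho02 = rho02, rho20 = rho20, chain = chain, stats = stats)
}
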