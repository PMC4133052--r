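# Internal: build the carrying-capacity vector and initial 3 x D count
# matrix implied by the specs. Every deme starts monomorphic for genotype
# '0' at its equilibrium occupancy (round(K (1 - g)) under the
# carrying-capacity scheme; exactly N under the fixed-N scheme).
build_initial_state <- function(landscape, deme, metapop, scheme) {
  g <- deme$g
  if (metapop$topology == "hub-and-spoke") {
    N_demes <- c(metapop$N_large, rep(metapop$N_island, metapop$C))
    K <- round(N_demes / (1 - g))
  } else {
    N_demes <- rep(deme$N, metapop$D)
    K <- rep(deme$K, metapop$D)
  }
  sizes <- if (scheme == "fixed-N") N_demes else round(K * (1 - g))
  init <- rbind(as.integer(sizes), 0L, 0L)
  list(K = as.numeric(K), init = init)
}

sim_result <- function(raw, seed) {
  structure(list(
    status = raw$status,
    crossing_time = raw$crossing_time,
    censored = !identical(raw$status, "crossed"),
    first_deme_fix_time = raw$first_deme_fix_time,
    t_end = raw$t_end,
    absorbed_genotype = raw$absorbed_genotype,
    counts = c(divisions = raw$n_divisions, deaths = raw$n_deaths,
               mutations = raw$n_mutations, migrations = raw$n_migrations,
               noop_migrations = raw$n_noop_migrations),
    n_events = raw$n_events,
    final_counts = raw$final_counts,
    seed = seed
  ), class = "crossing_result")
}

#' Simulate valley or plateau crossing by a metapopulation
#'
#' Exact Gillespie simulation of the metapopulation under the
#' carrying-capacity scheme: each individual of genotype `i` in deme `d`
#' divides at rate `f_i max(0, 1 - N_d/K)` (logistic growth; the offspring
#' mutates forward with probability `mu`), dies at rate `g`, and migration
#' events swap one uniformly chosen individual between two demes. All demes
#' start monomorphic for genotype `0` at equilibrium occupancy. The run
#' ends when every individual carries genotype `2` (the crossing time) or
#' at `t_max` (censored).
#'
#' @param landscape A [fitness_landscape()].
#' @param deme A [deme_spec()].
#' @param metapop A [metapop_spec()] (all-pairs or hub-and-spoke).
#' @param seed Integer seed (`set.seed` is called when non-`NULL`).
#' @param t_max Censoring horizon in simulation time units (default `1e9`).
#' @param init Optional `3 x D` integer matrix of initial genotype counts
#'   (rows = genotypes `0,1,2`), overriding the monomorphic start.
#' @param stop_when_monomorphic With `mu = 0`, stop as soon as the whole
#'   metapopulation is monomorphic for any genotype (used for fixation
#'   experiments). Default `FALSE`.
#' @param stop_at_first_fix Stop as soon as one deme is fixed for genotype
#'   `2` (status `"first_fix"`), for champion-deme experiments that do not
#'   need the full crossing. Default `FALSE`.
#' @param max_events Hard cap on the number of simulated events.
#' @return A `crossing_result`: `status` (`"crossed"`, `"censored"`,
#'   `"degenerate"`, `"absorbed"`, `"event_cap"`), `crossing_time`,
#'   `censored`, `first_deme_fix_time` (when the first deme fixed `2`),
#'   event `counts`, `final_counts` and the `seed` used.
#' @seealso [simulate_fixed_N()], [run_replicates()], [sweep_crossing()]
#' @export
simulate_crossing <- function(landscape, deme, metapop, seed = NULL,
                              t_max = 1e9, init = NULL,
                              stop_when_monomorphic = FALSE,
                              stop_at_first_fix = FALSE,
                              max_events = 2e10) {
  stopifnot(inherits(landscape, "fitness_landscape"),
            inherits(deme, "deme_spec"), inherits(metapop, "metapop_spec"))
  stop_invalid(t_max > 0, "t_max", "must be > 0")
  if (!is.null(seed)) set.seed(seed)
  st <- build_initial_state(landscape, deme, metapop, "carrying-capacity")
  if (!is.null(init)) {
    stopifnot(is.matrix(init), nrow(init) == 3)
    st$init <- matrix(as.integer(init), nrow = 3)
  }
  raw <- sim_crossing_cpp(
    st$init, st$K, landscape$f, deme$g, landscape$mu, metapop$m,
    metapop$migration_factor,
    topology = if (metapop$topology == "hub-and-spoke") 1L else 0L,
    m_total = if (!is.null(metapop$m_total_island)) metapop$m_total_island else 0,
    scheme = 0L, t_max = t_max,
    stop_when_monomorphic = stop_when_monomorphic,
    stop_at_first_fix = stop_at_first_fix, max_events = max_events)
  if (identical(raw$status, "degenerate")) {
    warning("metapopulation went extinct before crossing", call. = FALSE)
  }
  sim_result(raw, seed)
}

#' Simulate crossing with fixed deme sizes (Moran validation scheme)
#'
#' Alternative simulation scheme used only for cross-validation: deme sizes
#' are held exactly constant and each deme undergoes Moran replacement
#' events at rate `N g` (divider chosen proportional to fitness, a
#' uniformly chosen individual removed), with the same mutation and
#' migration semantics as [simulate_crossing()]. Valid as long as the total
#' migration rate is much smaller than the total replacement rate
#' (`m << g`); a warning is emitted otherwise.
#'
#' @inheritParams simulate_crossing
#' @return A `crossing_result`, as for [simulate_crossing()].
#' @export
simulate_fixed_N <- function(landscape, deme, metapop, seed = NULL,
                             t_max = 1e9, init = NULL,
                             stop_when_monomorphic = FALSE,
                             stop_at_first_fix = FALSE,
                             max_events = 2e10) {
  stopifnot(inherits(landscape, "fitness_landscape"),
            inherits(deme, "deme_spec"), inherits(metapop, "metapop_spec"))
  if (metapop$m >= deme$g) {
    warning("fixed-N scheme assumes migration far rarer than replacement ",
            "(m << g); results may be biased", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  st <- build_initial_state(landscape, deme, metapop, "fixed-N")
  if (!is.null(init)) {
    stopifnot(is.matrix(init), nrow(init) == 3)
    st$init <- matrix(as.integer(init), nrow = 3)
  }
  raw <- sim_crossing_cpp(
    st$init, st$K, landscape$f, deme$g, landscape$mu, metapop$m,
    metapop$migration_factor,
    topology = if (metapop$topology == "hub-and-spoke") 1L else 0L,
    m_total = if (!is.null(metapop$m_total_island)) metapop$m_total_island else 0,
    scheme = 1L, t_max = t_max,
    stop_when_monomorphic = stop_when_monomorphic,
    stop_at_first_fix = stop_at_first_fix, max_events = max_events)
  sim_result(raw, seed)
}

#' Run independent replicate simulations and summarise crossing times
#'
#' Replicates are fully independent: a deterministic stream of child seeds
#' is drawn from `base_seed`, so the same `base_seed` reproduces every
#' replicate bit for bit. Censored replicates are excluded from the mean
#' and reported separately. The 95% confidence interval uses the normal
#' approximation `mean +/- 1.96 se`.
#'
#' @inheritParams simulate_crossing
#' @param n_replicates Number of replicates (`>= 1`).
#' @param base_seed Integer master seed.
#' @param scheme `"carrying-capacity"` (default) or `"fixed-N"`.
#' @return A list of class `sample_summary`: `summary` (one-row data frame
#'   with `n_replicates`, `mean`, `se`, `ci_low`, `ci_high`, `censored_n`,
#'   `mean_first_fix`) and `replicates` (one row per replicate).
#' @export
run_replicates <- function(landscape, deme, metapop, n_replicates, base_seed,
                           t_max = 1e9,
                           scheme = c("carrying-capacity", "fixed-N"),
                           init = NULL, stop_at_first_fix = FALSE,
                           max_events = 2e10) {
  scheme <- match.arg(scheme)
  stop_invalid(n_replicates >= 1, "n_replicates", "must be >= 1")
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  fn <- if (scheme == "fixed-N") simulate_fixed_N else simulate_crossing
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    r <- fn(landscape, deme, metapop, seed = seeds[i], t_max = t_max,
            init = init, stop_at_first_fix = stop_at_first_fix,
            max_events = max_events)
    rows[[i]] <- data.frame(
      replicate = i, seed = seeds[i],
      crossing_time = if (is.na(r$crossing_time)) NA_real_ else r$crossing_time,
      censored = r$censored,
      first_deme_fix_time = r$first_deme_fix_time,
      n_divisions = r$counts[["divisions"]],
      n_deaths = r$counts[["deaths"]],
      n_mutations = r$counts[["mutations"]],
      n_migrations = r$counts[["migrations"]]
    )
  }
  reps <- do.call(rbind, rows)
  structure(list(summary = summarize_replicates(reps), replicates = reps),
            class = "sample_summary")
}

summarize_replicates <- function(reps) {
  tt <- reps$crossing_time[!reps$censored]
  n_ok <- length(tt)
  m <- if (n_ok) mean(tt) else NA_real_
  se <- if (n_ok > 1) stats::sd(tt) / sqrt(n_ok) else NA_real_
  data.frame(
    n_replicates = nrow(reps),
    mean = m, se = se,
    ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
    censored_n = sum(reps$censored),
    mean_first_fix = mean(reps$first_deme_fix_time, na.rm = TRUE)
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "crossing time over %d replicates: mean %.4g [95%% CI %.4g, %.4g], %d censored\n",
    s$n_replicates, s$mean, s$ci_low, s$ci_high, s$censored_n))
  invisible(x)
}

#' Parameter sweep over a simulation axis
#'
#' Runs [run_replicates()] on a grid along one axis and returns a long
#' table with the simulation summary and the matching theory predictions
#' joined per grid point:
#' \describe{
#'   \item{`m_over_mu`}{migration-to-mutation rate ratio (all-pairs).}
#'   \item{`delta`}{valley depth at fixed everything else.}
#'   \item{`D_at_fixed_total_K`}{number of demes, holding the total carrying
#'     capacity `D * K` of the current configuration fixed (per-deme
#'     `K = round(K_total / D)`).}
#'   \item{`N_island`}{island size of a hub-and-spoke configuration, with
#'     the axis grid interpreted as `m_total_island / mu` instead when the
#'     topology is hub-and-spoke and the axis is `m_over_mu`.}
#' }
#' Failed grid points are flagged (`failed = TRUE`) and the sweep continues.
#'
#' @inheritParams run_replicates
#' @param axis One of `"m_over_mu"`, `"delta"`, `"D_at_fixed_total_K"`,
#'   `"N_island"`.
#' @param grid Numeric vector of axis values (non-empty).
#' @return A data frame with columns `axis_name`, `axis_value`,
#'   `n_replicates`, `mean`, `ci_low`, `ci_high`, `censored_n`, `failed`,
#'   `theory_tau_champion`, `theory_window_min`, `theory_window_max`.
#' @export
sweep_crossing <- function(landscape, deme, metapop, axis, grid,
                           n_replicates, base_seed, t_max = 1e9,
                           scheme = c("carrying-capacity", "fixed-N"),
                           max_events = 2e10) {
  scheme <- match.arg(scheme)
  axis <- match.arg(axis, c("m_over_mu", "delta", "D_at_fixed_total_K",
                            "N_island"))
  stop_invalid(length(grid) >= 1, "grid", "must be non-empty")
  set.seed(base_seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, length(grid))
  K_total <- deme$K * metapop$D
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    v <- grid[i]
    cfg <- tryCatch({
      ls_i <- landscape; dm_i <- deme; mp_i <- metapop
      if (axis == "m_over_mu") {
        if (metapop$topology == "hub-and-spoke") {
          mp_i$m_total_island <- v * landscape$mu
        } else {
          mp_i$m <- v * landscape$mu
        }
      } else if (axis == "delta") {
        ls_i <- fitness_landscape(v, landscape$s, landscape$mu)
      } else if (axis == "D_at_fixed_total_K") {
        dm_i <- deme_spec(K = round(K_total / v), g = deme$g)
        mp_i <- metapop_spec(D = v, m = metapop$m,
                             migration_factor = metapop$migration_factor)
      } else if (axis == "N_island") {
        mp_i$N_island <- v
      }
      list(ls = ls_i, dm = dm_i, mp = mp_i)
    }, error = function(e) NULL)
    theory <- if (!is.null(cfg)) tryCatch({
      if (cfg$mp$topology == "hub-and-spoke") {
        w <- island_window(cfg$mp$N_large, cfg$mp$N_island, cfg$mp$C,
                           cfg$ls, cfg$dm$g, warn = FALSE)
        list(tau = w$tau_f, wmin = w$m_over_mu_min, wmax = w$m_over_mu_max)
      } else {
        w <- migration_window(cfg$ls, cfg$dm$N, cfg$mp$D, cfg$dm$g,
                              migration_factor = cfg$mp$migration_factor,
                              warn = FALSE)
        list(tau = w$tau_f, wmin = w$m_over_mu_min, wmax = w$m_over_mu_max)
      }
    }, error = function(e) list(tau = NA_real_, wmin = NA_real_,
                                wmax = NA_real_))
    else list(tau = NA_real_, wmin = NA_real_, wmax = NA_real_)
    res <- if (!is.null(cfg)) tryCatch(
      run_replicates(cfg$ls, cfg$dm, cfg$mp, n_replicates,
                     base_seed = point_seeds[i], t_max = t_max,
                     scheme = scheme, max_events = max_events),
      error = function(e) NULL
    )
    s <- if (!is.null(res)) res$summary else
      data.frame(n_replicates = 0L, mean = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 censored_n = NA_integer_, mean_first_fix = NA_real_)
    out[[i]] <- data.frame(
      axis_name = axis, axis_value = v,
      n_replicates = s$n_replicates, mean = s$mean,
      ci_low = s$ci_low, ci_high = s$ci_high,
      censored_n = s$censored_n, failed = is.null(res),
      theory_tau_champion = theory$tau, theory_window_min = theory$wmin,
      theory_window_max = theory$wmax
    )
    message(sprintf("sweep %s = %g: mean %.4g (%d replicates, %s censored)",
                    axis, v, s$mean, s$n_replicates,
                    as.character(s$censored_n)))
  }
  do.call(rbind, out)
}
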