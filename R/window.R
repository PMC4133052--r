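#' Optimal migration-rate window for a subdivided population
#'
#' Migration must be rare enough for demes to cross quasi-independently,
#' yet frequent enough for the final beneficial mutation to spread quickly
#' once the champion deme has fixed it. With migration events occurring at
#' total rate `M_tot = m N D / migration_factor` (default factor 2: each
#' event relocates two individuals, so each individual migrates at rate
#' `m`), the two conditions are
#' \describe{
#'   \item{quasi-independence (upper bound)}{the time
#'     `tau_fix2 = 1/(N mu g rho12)` for a `1`-fixed deme to fix the final
#'     mutation must beat the migration-driven extinction time
#'     `tau_e = n_e / M_tot`, giving
#'     `m/mu < migration_factor * g * rho12 * n_e / D`;}
#'   \item{rapid spreading (lower bound)}{the spreading time
#'     `tau_s = n_f / M_tot` must beat the champion crossing time `tau_f`
#'     ([champion_mean_time()]), giving
#'     `m/mu > migration_factor * n_f / (N D mu tau_f)`.}
#' }
#' Both bounds are computed from the general chain-based `n_e`, `n_f`
#' ([n_extinction()], [n_spreading()]) -- important because subdivision is
#' typically most beneficial at intermediate `N delta` -- and also in the
#' simplified form using the closed-form `n_e`, `n_f` estimates.
#'
#' @param landscape A [fitness_landscape()].
#' @param N Deme size.
#' @param D Number of demes (`>= 2` for a window to exist).
#' @param g Turnover rate per individual.
#' @param migration_factor Total-rate convention constant (default 2).
#' @param warn Warn when demes are not in the sequential-fixation regime
#'   (the window is meaningless when isolated demes tunnel).
#' @return List of class `migration_window`: `m_over_mu_min`,
#'   `m_over_mu_max`, `ratio` (`R = max/min`), `exists` (`R > 1`), the
#'   simplified-bound variants (`..._approx`), and the ingredients
#'   `tau_fix2`, `tau_f`, `n_e`, `n_f`, `rho`'s and the convention used.
#' @export
migration_window <- function(landscape, N, D, g, migration_factor = 2,
                             warn = TRUE) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  stop_invalid(g > 0, "g", "must be > 0")
  if (D < 2) {
    return(structure(list(exists = FALSE, D = D,
                          m_over_mu_min = NA_real_, m_over_mu_max = NA_real_,
                          ratio = NA_real_,
                          note = "no migration partners for D < 2"),
                     class = "migration_window"))
  }
  reg <- classify_regime(landscape, N, g)
  if (warn && reg$regime != "sequential") {
    warning("isolated demes (N = ", N, ") are in the tunneling regime: ",
            "subdivision cannot significantly accelerate crossing and the ",
            "migration window is not meaningful", call. = FALSE)
  }
  mu <- landscape$mu
  seqp <- sequential_prediction(landscape, N, g)
  ext <- n_extinction(landscape, N, D, warn = FALSE)
  spr <- n_spreading(landscape, N, D, warn = FALSE)
  tau_fix2 <- 1 / seqp$rate2
  tau_f <- champion_mean_time(seqp$rate1, seqp$rate2, D)

  # upper bound: tau_fix2 < tau_e = n_e * migration_factor / (m N D)
  upper <- function(n_e) migration_factor * n_e / (N * D * mu * tau_fix2)
  # lower bound: tau_s = n_f * migration_factor / (m N D) < tau_f
  lower <- function(n_f) migration_factor * n_f / (N * D * mu * tau_f)

  m_max <- upper(ext$n_e)
  m_min <- lower(spr$n_f)
  m_max_a <- upper(ext$n_e_simplified)
  m_min_a <- lower(spr$n_f_simplified)
  structure(list(
    m_over_mu_min = m_min, m_over_mu_max = m_max,
    ratio = m_max / m_min, exists = m_max > m_min,
    m_over_mu_min_approx = m_min_a, m_over_mu_max_approx = m_max_a,
    ratio_approx = m_max_a / m_min_a,
    tau_fix2 = tau_fix2, tau_f = tau_f,
    tau_e_at = function(m) migration_factor * ext$n_e / (m * N * D),
    tau_s_at = function(m) migration_factor * spr$n_f / (m * N * D),
    n_e = ext$n_e, n_f = spr$n_f,
    n_e_simplified = ext$n_e_simplified, n_f_simplified = spr$n_f_simplified,
    rho01 = ext$rho01, rho10 = ext$rho10,
    rho02 = spr$rho02, rho12 = seqp$rho12,
    regime_deme = reg$regime, D = D, N = N, g = g, mu = mu,
    migration_factor = migration_factor
  ), class = "migration_window")
}

#' @export
print.migration_window <- function(x, ...) {
  if (!isTRUE(x$exists) && is.na(x$m_over_mu_min)) {
    cat("migration window: not applicable (", x$note, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("migration window (m/mu): [%.4g, %.4g], ratio R = %.4g (%s)\n",
              x$m_over_mu_min, x$m_over_mu_max, x$ratio,
              if (x$exists) "exists" else "empty"))
  invisible(x)
}

#' Widest achievable window under the sequential-fixation constraint
#'
#' Isolated demes must remain in the sequential-fixation regime, which caps
#' the deme size at `N_threshold` ([classify_regime()]); since the window
#' ratio `R` grows with `N`, the widest achievable window for a given
#' landscape and deme count is attained just below that threshold. The
#' threshold and `R` are composed numerically, with no closed-form
#' assumptions.
#'
#' @inheritParams migration_window
#' @return List: `N_threshold`, `R_max` (the window ratio at
#'   `floor(N_threshold)`), and `window` (the [migration_window()] there).
#'   `R_max` is `NA` when the threshold is below 2 individuals.
#' @export
window_ratio_bound <- function(landscape, D, g, migration_factor = 2) {
  reg <- classify_regime(landscape, N = 100, g = g)
  N_thr <- reg$N_threshold
  if (is.na(N_thr) || N_thr < 2) {
    return(list(N_threshold = N_thr, R_max = NA_real_, window = NULL))
  }
  w <- migration_window(landscape, N = floor(N_thr), D = D, g = g,
                        migration_factor = migration_factor, warn = FALSE)
  list(N_threshold = N_thr, R_max = w$ratio, window = w)
}

#' Best-scenario speedup of valley or plateau crossing by subdivision
#'
#' In the best possible scenario the metapopulation crossing time equals
#' that of its champion deme, `tau_champion`. This report assembles the
#' crossing times of an isolated deme, the champion, and the equally-sized
#' non-subdivided population (`N D` individuals), the resulting speedup
#' ratios, the applicable closed-form ratio, and the necessary condition
#' `tau_deme / D < tau_nonsub` for subdivision to help at all. When the
#' non-subdivided population tunnels, the best-scenario ratio is `p1 /
#' rho01` -- always below 1 for sequential demes -- specialising to
#' `N sqrt(mu s_est)` on a plateau and to `(mu s_est / delta^2)-type`
#' growth for deep valleys; when isolated demes themselves tunnel,
#' subdivision cannot accelerate crossing and a `no_speedup` flag is set.
#'
#' @inheritParams migration_window
#' @return List of class `speedup_report`.
#' @export
speedup_report <- function(landscape, N, D, g) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  reg_deme <- classify_regime(landscape, N, g)
  seqp <- sequential_prediction(landscape, N, g)
  tau_deme <- min(reg_deme$sequential_mean, reg_deme$tunneling_mean)
  tau_champion <- champion_mean_time(seqp$rate1, seqp$rate2, D)
  tau_best <- tau_deme / D                      # idealised one-step champion
  nonsub <- nonsubdivided_time(landscape, N * D, g)
  ts <- tunneling_success_probability(landscape)
  rho01_deme <- seqp$rho01
  rho01_total <- fixation_probability(landscape$f[1], landscape$f[2], N * D)

  deme_sequential <- reg_deme$regime == "sequential"
  ratio_closed <- if (!deme_sequential) {
    NA_real_                                    # no speedup regime
  } else if (nonsub$regime == "sequential") {
    rho01_total / (D * rho01_deme)              # both sequential
  } else {
    ts$p1 / rho01_deme                          # non-subdivided tunnels
  }
  ratio_plateau <- N * sqrt(landscape$mu * ts$s_est)
  structure(list(
    tau_deme = tau_deme, tau_champion = tau_champion, tau_best = tau_best,
    tau_nonsub = nonsub$mean_time,
    ratio_best = tau_champion / nonsub$mean_time,
    ratio_best_ideal = tau_best / nonsub$mean_time,
    ratio_closed_form = ratio_closed,
    ratio_plateau_form = ratio_plateau,
    regime_deme = reg_deme$regime, regime_nonsub = nonsub$regime,
    p1 = ts$p1, rho01 = rho01_deme,
    necessary_condition = tau_deme / D < nonsub$mean_time,
    no_speedup = !deme_sequential,
    D = D, N = N
  ), class = "speedup_report")
}

#' Valley depth giving the largest speedup by subdivision
#'
#' When the non-subdivided population tunnels while demes fix sequentially,
#' the best-scenario speedup ratio has the deep-valley structure
#' `r(delta) = (mu s_est / delta^2) e^{N delta}` (success probability of a
#' tunneling intermediate over the drift-suppressed fixation probability of
#' a deleterious intermediate). This ratio is minimised numerically over
#' `delta`; the analytic stationary point `delta* = 2/N`, with minimum
#' `e^2 mu s_est N^2 / 4`, initialises and cross-checks the search.
#'
#' @param mu Mutation probability per division.
#' @param s_est Establishment probability of the final genotype.
#' @param N Deme size (`>= 10`, so a deep-valley regime is reachable).
#' @param delta_max Upper end of the search interval (default 1).
#' @return List: `delta_star`, `ratio_min`, and the analytic references
#'   `delta_star_analytic = 2/N`, `ratio_min_analytic`.
#' @export
optimal_valley_depth <- function(mu, s_est, N, delta_max = 1) {
  stop_invalid(mu > 0 && mu < 1, "mu", "must lie in (0, 1)")
  stop_invalid(s_est > 0, "s_est", "must be > 0")
  stop_invalid(N >= 10, "N", "deep-valley optimum needs N >= 10")
  obj <- function(delta) log(mu * s_est) - 2 * log(delta) + N * delta
  opt <- stats::optimize(obj, interval = c(1e-8, delta_max), tol = 1e-12)
  at_edge <- opt$minimum < 2e-8 || opt$minimum > delta_max * (1 - 1e-6)
  if (at_edge) {
    stop(structure(class = c("optimization_failure", "error", "condition"),
                   list(message = "optimal_valley_depth: no interior minimum",
                        call = sys.call())))
  }
  list(delta_star = opt$minimum,
       ratio_min = exp(opt$objective),
       delta_star_analytic = 2 / N,
       ratio_min_analytic = exp(2) * mu * s_est * N^2 / 4)
}

#' Migration window for a large population coupled to satellite islands
#'
#' Hub-and-spoke analogue of [migration_window()]: a large population of
#' `N_large` individuals exchanges migrants with `C` islands of `N_island`
#' individuals each (islands in the sequential-fixation regime), at total
#' event rate `m_I`, the island being chosen uniformly per event. The
#' quasi-independence condition compares the island's time to fix the final
#' mutation with its migration-driven extinction time
#' `C / (m_I rho_ext)` (`rho_ext` = fixation probability of a wild-type
#' migrant among `N_island` intermediates); the rapid-spreading condition
#' compares the spreading time `C / (m_I rho02)` into the large population
#' with the champion-island crossing time ([champion_mean_time()] with `C`
#' islands).
#'
#' @param N_large,N_island,C Hub-and-spoke geometry (`N_island < N_large`).
#' @param landscape A [fitness_landscape()].
#' @param g Turnover rate per individual.
#' @param warn Warn when islands are not in the sequential regime.
#' @return List of class `migration_window` with bounds on `m_I / mu`.
#' @export
island_window <- function(N_large, N_island, C, landscape, g, warn = TRUE) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  stop_invalid(N_island < N_large, "N_island", "must be smaller than N_large")
  stop_invalid(C >= 1 && C == round(C), "C", "must be an integer >= 1")
  reg <- classify_regime(landscape, N_island, g)
  if (warn && reg$regime != "sequential") {
    warning("islands (N = ", N_island, ") are in the tunneling regime",
            call. = FALSE)
  }
  mu <- landscape$mu
  f <- landscape$f
  seqp <- sequential_prediction(landscape, N_island, g)
  rho_ext <- fixation_probability(f[2], f[1], N_island)   # 1/N on a plateau
  rho02_large <- fixation_probability(f[1], f[3], N_large)
  tau_fix2 <- 1 / seqp$rate2
  tau_f <- champion_mean_time(seqp$rate1, seqp$rate2, C)
  m_max <- C / (rho_ext * tau_fix2 * mu)     # from tau_fix2 < C/(m_I rho_ext)
  m_min <- C / (rho02_large * tau_f * mu)    # from C/(m_I rho02) < tau_f
  structure(list(
    m_over_mu_min = m_min, m_over_mu_max = m_max,
    ratio = m_max / m_min, exists = m_max > m_min,
    tau_fix2 = tau_fix2, tau_f = tau_f, tau_island = seqp$mean_time,
    rho_ext = rho_ext, rho02_large = rho02_large,
    regime_island = reg$regime,
    N_large = N_large, N_island = N_island, C = C, g = g, mu = mu,
    topology = "hub-and-spoke"
  ), class = "migration_window")
}

#' Assemble a machine-readable theory report
#'
#' Gathers the validity flags, regimes, crossing-time predictions,
#' migration-event counts, window bounds and speedup ratios for one
#' parameter set into a JSON-serialisable list (stable key names,
#' versioned).
#'
#' @param landscape A [fitness_landscape()].
#' @param deme A [deme_spec()].
#' @param metapop A [metapop_spec()].
#' @return A nested list of class `theory_report`.
#' @export
theory_report <- function(landscape, deme, metapop) {
  flags <- validate_model(landscape, deme, metapop)
  N <- deme$N; g <- deme$g; D <- metapop$D
  seqp <- sequential_prediction(landscape, N, g)
  sp <- speedup_report(landscape, N, D, g)
  win <- if (metapop$topology == "hub-and-spoke") {
    island_window(metapop$N_large, metapop$N_island, metapop$C, landscape, g,
                  warn = FALSE)
  } else {
    migration_window(landscape, N, D, g,
                     migration_factor = metapop$migration_factor, warn = FALSE)
  }
  depth <- if (N >= 10) {
    tryCatch(optimal_valley_depth(landscape$mu, landscape$s / (1 + landscape$s), N),
             error = function(e) NULL)
  }
  structure(list(
    version = "1",
    params = list(delta = landscape$delta, s = landscape$s, mu = landscape$mu,
                  K = deme$K, g = g, N = N, D = D, m = metapop$m,
                  topology = metapop$topology),
    validity_flags = flags[c("effective_neutrality", "low_migration",
                             "mutation_supply_ok")],
    regimes = list(deme = sp$regime_deme, nonsubdivided = sp$regime_nonsub),
    rates = list(rate1 = seqp$rate1, rate2 = seqp$rate2,
                 rho01 = seqp$rho01, rho12 = seqp$rho12),
    tau = list(deme = sp$tau_deme, champion = sp$tau_champion,
               nonsubdivided = sp$tau_nonsub),
    n_events = if (!is.null(win$n_e)) {
      list(extinction = win$n_e, spreading = win$n_f)
    },
    window = list(min = win$m_over_mu_min, max = win$m_over_mu_max,
                  ratio = win$ratio, exists = isTRUE(win$exists),
                  convention = if (!is.null(win$migration_factor))
                    win$migration_factor else "hub-and-spoke"),
    speedups = list(best_ratio = sp$ratio_best,
                    best_ratio_ideal = sp$ratio_best_ideal,
                    closed_form = sp$ratio_closed_form,
                    necessary_condition = sp$necessary_condition,
                    no_speedup = sp$no_speedup),
    delta_star = if (!is.null(depth)) depth$delta_star else NA_real_
  ), class = "theory_report")
}
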