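#' Moran fixation probability of a single mutant
#'
#' Probability that the lineage of a single individual with fitness
#' `f_mutant` fixes in a well-mixed population of `N` individuals whose
#' other `N - 1` members have fitness `f_resident`:
#' \deqn{\rho = \frac{1 - f_{res}/f_{mut}}{1 - (f_{res}/f_{mut})^N},}
#' the classical Moran result, with the neutral limit `1/N`. The
#' implementation works on `x = log(f_mut/f_res)` using `expm1`, so the
#' neutral branch is approached continuously to machine precision, and
#' switches to a log-space form when `(f_res/f_mut)^N` would overflow
#' (strongly deleterious invaders in large populations).
#'
#' @param f_resident,f_mutant Fitnesses (`> 0`). Vectorised.
#' @param N Population size (`>= 2`).
#' @return Fixation probability in `(0, 1)`.
#' @examples
#' fixation_probability(1, 1, 100)    # 1/N = 0.01
#' fixation_probability(1, 1.1, 10)   # beneficial invader, ~0.148
#' fixation_probability(1, 0.9, 10)   # deleterious invader, ~0.0595
#' @export
fixation_probability <- function(f_resident, f_mutant, N) {
  stop_invalid(all(is.finite(f_resident)) && all(f_resident > 0),
               "f_resident", "must be positive")
  stop_invalid(all(is.finite(f_mutant)) && all(f_mutant > 0),
               "f_mutant", "must be positive")
  stop_invalid(all(N >= 2), "N", "must be >= 2")
  x <- log(f_mutant) - log(f_resident)
  rho <- ifelse(
    x == 0,
    1 / N,
    ifelse(
      N * x < -700,
      # denominator expm1(-Nx) ~ e^{-Nx} overflows: rho ~ expm1(-x) e^{Nx}
      expm1(-x) * exp(N * x),
      expm1(-x) / expm1(-N * x)
    )
  )
  as.numeric(rho)
}

#' Crossing-time prediction in the sequential-fixation regime
#'
#' In a small population the intermediate mutation `1` first fixes (rate
#' `rate1 = N mu g rho01`), then the beneficial mutation `2` fixes
#' (rate `rate2 = N mu g rho12`): `N mu g` is the total mutation supply per
#' unit time (each of `N` individuals turns over at rate `g` and each
#' division mutates with probability `mu`) and `rho` the Moran fixation
#' probabilities. The crossing time is hypoexponential with mean
#' `1/rate1 + 1/rate2`.
#'
#' @param landscape A [fitness_landscape()].
#' @param N Deme size.
#' @param g Turnover (death) rate per individual.
#' @return List of class `sequential_prediction`: `rate1`, `rate2`,
#'   `mean_time`, and the fixation probabilities `rho01`, `rho12`.
#' @export
sequential_prediction <- function(landscape, N, g) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  stop_invalid(N >= 2, "N", "must be >= 2")
  stop_invalid(g > 0, "g", "must be > 0")
  stop_invalid(landscape$mu > 0, "mu", "must be > 0")
  f <- landscape$f
  rho01 <- fixation_probability(f[1], f[2], N)
  rho12 <- fixation_probability(f[2], f[3], N)
  rate1 <- N * landscape$mu * g * rho01
  rate2 <- N * landscape$mu * g * rho12
  structure(list(rate1 = rate1, rate2 = rate2,
                 mean_time = 1 / rate1 + 1 / rate2,
                 rho01 = rho01, rho12 = rho12),
            class = "sequential_prediction")
}

#' Probability that an intermediate mutant is "successful" (tunneling)
#'
#' Branching-process approximation for the probability `p1` that the lineage
#' spawned by a single `1`-mutant produces a `2`-mutant that establishes,
#' without the intermediate ever fixing:
#' \deqn{p_1 = \frac{-\delta + \sqrt{\delta^2 + 4 \mu s_{est}}}{2},}
#' where `s_est` is the establishment probability of genotype `2`
#' (default `s / (1 + s)`, the continuous-time branching result). Limits:
#' `sqrt(mu * s_est)` on a plateau, `mu * s_est / delta` for a deep valley
#' (`delta >> sqrt(mu * s_est)`).
#'
#' @param landscape A [fitness_landscape()].
#' @param s_est Optional override of the establishment probability.
#' @return List: `p1`, `s_est` and `regime`, one of `"plateau-like"`,
#'   `"intermediate"`, `"deep-valley"` according to `delta / sqrt(mu s_est)`.
#' @export
tunneling_success_probability <- function(landscape, s_est = NULL) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  delta <- landscape$delta
  stop_invalid(delta < 1, "delta", "must be < 1")
  if (is.null(s_est)) s_est <- landscape$s / (1 + landscape$s)
  if (landscape$mu == 0) {
    return(list(p1 = 0, s_est = s_est, regime = "degenerate"))
  }
  scale <- sqrt(landscape$mu * s_est)
  p1 <- (-delta + sqrt(delta^2 + 4 * landscape$mu * s_est)) / 2
  regime <- if (abs(delta) <= 0.1 * scale) "plateau-like"
            else if (delta >= 10 * scale) "deep-valley"
            else "intermediate"
  list(p1 = p1, s_est = s_est, regime = regime)
}

#' Crossing-time prediction in the stochastic-tunneling regime
#'
#' In a large population the beneficial mutation arises on a transient
#' minority lineage of intermediates and fixes without the intermediate
#' ever fixing. Crossing is then a single event with constant rate
#' `N mu g p1`, so the crossing time is exponential with mean
#' `1 / (N mu g p1)`.
#'
#' @inheritParams sequential_prediction
#' @param s_est Optional establishment-probability override, passed to
#'   [tunneling_success_probability()].
#' @param supply_tol Warn when `N mu` exceeds this (lineage competition
#'   invalidates the single-event picture). Default 0.1.
#' @return List of class `tunneling_prediction`: `p1`, `mean_time`, `rate`.
#' @export
tunneling_prediction <- function(landscape, N, g, s_est = NULL,
                                 supply_tol = 0.1) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  stop_invalid(N >= 2, "N", "must be >= 2")
  stop_invalid(g > 0, "g", "must be > 0")
  stop_invalid(landscape$mu > 0, "mu", "must be > 0 (no path to genotype '2')")
  if (N * landscape$mu > supply_tol) {
    warning("N * mu = ", signif(N * landscape$mu, 3),
            ": mutant lineages may compete; the constant-rate tunneling ",
            "approximation assumes N * mu << 1", call. = FALSE)
  }
  ts <- tunneling_success_probability(landscape, s_est)
  rate <- N * landscape$mu * g * ts$p1
  structure(list(p1 = ts$p1, s_est = ts$s_est, rate = rate,
                 mean_time = 1 / rate, regime = ts$regime),
            class = "tunneling_prediction")
}

#' Classify the crossing regime of a well-mixed population
#'
#' Compares the sequential-fixation and tunneling mean crossing times at
#' size `N` and locates, by bisection in `log N`, the threshold size at
#' which the two predictions cross. Sequential fixation dominates below the
#' threshold (drift lets the intermediate fix), tunneling above it.
#'
#' @inheritParams sequential_prediction
#' @param N_max Upper bracket for the threshold search (default `1e9`).
#' @return List of class `regime_report`: `regime` (`"sequential"` or
#'   `"tunneling"`), `sequential_mean`, `tunneling_mean`, `N_threshold`
#'   (`NA` if the predictions do not cross in `[2, N_max]`).
#' @export
classify_regime <- function(landscape, N, g, N_max = 1e9) {
  seqp <- sequential_prediction(landscape, N, g)
  tunp <- tunneling_prediction(landscape, N, g, supply_tol = Inf)
  gap <- function(n) {
    log(sequential_prediction(landscape, n, g)$mean_time) -
      log(tunneling_prediction(landscape, n, g, supply_tol = Inf)$mean_time)
  }
  N_threshold <- NA_real_
  g2 <- gap(2); gM <- gap(N_max)
  if (is.finite(g2) && is.finite(gM) && g2 * gM < 0) {
    N_threshold <- exp(stats::uniroot(function(z) gap(exp(z)),
                                      lower = log(2), upper = log(N_max),
                                      tol = 1e-10)$root)
  }
  structure(list(
    regime = if (seqp$mean_time < tunp$mean_time) "sequential" else "tunneling",
    sequential_mean = seqp$mean_time,
    tunneling_mean = tunp$mean_time,
    N_threshold = N_threshold
  ), class = "regime_report")
}

#' Mean crossing time of the champion deme
#'
#' Mean of the minimum of `D` i.i.d. hypoexponential(`rate1`, `rate2`)
#' crossing times: the first of `D` independent demes to complete both
#' sequential-fixation steps. Computed by adaptive quadrature of the
#' survival function raised to the `D`-th power,
#' \eqn{\int_0^\infty S(t)^D dt}. When the second step is negligible
#' (`rate2/rate1` above `fastpath_threshold` and `D` not larger than
#' `rate2/rate1`) the exponential order-statistic identity `1/(D rate1)`
#' is returned instead; for very large `D` the second step limits the
#' champion and the quadrature path is always used.
#'
#' @param rate1,rate2 Rates of the two sequential steps (`> 0`).
#' @param D Number of independent demes (`>= 1`).
#' @param fastpath_threshold Rate ratio above which the one-step
#'   approximation is allowed (default 50).
#' @param rel_tol Relative tolerance of the quadrature (default 1e-8).
#' @return Mean crossing time of the fastest deme.
#' @export
champion_mean_time <- function(rate1, rate2, D, fastpath_threshold = 50,
                               rel_tol = 1e-8) {
  stop_invalid(rate1 > 0 && rate2 > 0, "rate", "rates must be > 0")
  stop_invalid(D >= 1 && D == round(D), "D", "must be an integer >= 1")
  if (D == 1) return(1 / rate1 + 1 / rate2)
  ratio <- rate2 / rate1
  if (ratio > fastpath_threshold && D <= ratio) {
    return(1 / (D * rate1))
  }
  S <- hypoexp_survival(rate1, rate2)
  # integrate S(t)^D on (0, Inf); substitute t = u / rate1 for conditioning
  f <- function(u) S(u / rate1)^D / rate1
  res <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) NULL
  )
  if (is.null(res) || res$message != "OK") {
    stop(structure(class = c("quadrature_failure", "error", "condition"),
                   list(message = "champion_mean_time: quadrature did not converge",
                        call = sys.call())))
  }
  res$value
}

# survival function of the hypoexponential(rate1, rate2) distribution,
# with a numerically stable branch for nearly equal rates
hypoexp_survival <- function(rate1, rate2) {
  if (abs(rate2 - rate1) < 1e-9 * rate1) {
    r <- (rate1 + rate2) / 2
    function(t) (1 + r * t) * exp(-r * t)
  } else {
    function(t) {
      (rate2 * exp(-rate1 * t) - rate1 * exp(-rate2 * t)) / (rate2 - rate1)
    }
  }
}

#' Crossing time of the equally-sized non-subdivided population
#'
#' Classifies the regime of a single well-mixed population of `N_total`
#' individuals and returns the faster prediction's mean crossing time:
#' the reference against which subdivision speedups are measured.
#'
#' @param landscape A [fitness_landscape()].
#' @param N_total Total population size.
#' @param g Turnover rate per individual.
#' @return List: `mean_time`, `regime`, and the underlying `regime_report`.
#' @export
nonsubdivided_time <- function(landscape, N_total, g) {
  rep <- classify_regime(landscape, N_total, g)
  list(
    mean_time = min(rep$sequential_mean, rep$tunneling_mean),
    regime = rep$regime,
    report = rep
  )
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("regime: %s (sequential mean %.4g, tunneling mean %.4g, N* ~ %.4g)\n",
              x$regime, x$sequential_mean, x$tunneling_mean, x$N_threshold))
  invisible(x)
}
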