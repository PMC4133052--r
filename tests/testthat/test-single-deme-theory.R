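test_that("fixation probability matches the Moran closed form and its limits", {
  # neutral limit is exactly 1/N
  expect_equal(fixation_probability(1, 1, 100), 0.01)
  expect_equal(fixation_probability(2, 2, 10), 0.1)
  # frozen values from independent evaluation of (1 - 1/w)/(1 - w^-N)
  expect_equal(fixation_probability(1, 1.1, 10), 0.1479503590, tolerance = 1e-8)
  expect_equal(fixation_probability(1, 0.9, 10), 0.0594822148, tolerance = 1e-8)
  expect_equal(fixation_probability(1, 1.01, 100), 0.0157086566,
               tolerance = 1e-8)
  expect_error(fixation_probability(1, 0, 10), class = "invalid_parameter")
  expect_error(fixation_probability(1, 1.1, 1), class = "invalid_parameter")
})

test_that("fixation probability is continuous through the neutral point", {
  N <- 50
  eps <- 10^seq(-14, -8)
  up <- fixation_probability(1, 1 + eps, N)
  dn <- fixation_probability(1, 1 - eps, N)
  expect_true(all(abs(up - 1 / N) < 1e-8))
  expect_true(all(abs(dn - 1 / N) < 1e-8))
  expect_true(all(up >= 1 / N & dn <= 1 / N))
})

test_that("detailed balance rho_ij/rho_ji = (f_j/f_i)^(N-1) holds to 1e-10", {
  fs <- c(0.8, 0.95, 1, 1.05, 1.3)
  for (N in c(2, 10, 100, 1000)) {
    for (fi in fs) for (fj in fs) {
      if (fi == fj) next
      lhs <- fixation_probability(fi, fj, N) / fixation_probability(fj, fi, N)
      rhs <- (fj / fi)^(N - 1)
      expect_lt(abs(lhs - rhs) / rhs, 1e-10)
    }
  }
})

test_that("sequential prediction reproduces the two-step rates", {
  ls <- fitness_landscape(0, 0.1, 1e-5)
  sp <- sequential_prediction(ls, 100, 0.1)
  expect_equal(sp$rate1, 100 * 1e-5 * 0.1 * (1 / 100))    # plateau: rho01=1/N
  expect_close(sp$rate2, 9.09e-6, 0.01)
  expect_close(sp$mean_time, 1.110e6, 0.01)
  expect_gt(sp$mean_time, max(1 / sp$rate1, 1 / sp$rate2))

  # s -> large: second step vanishes and mean -> 1/rate1
  ls_big_s <- fitness_landscape(0, 50, 1e-5)
  sp2 <- sequential_prediction(ls_big_s, 100, 0.1)
  expect_close(sp2$mean_time, 1 / sp2$rate1, 0.02)

  # valley example: rate1 = N mu g rho01 with rho01 ~ 3.135e-4
  spv <- sequential_prediction(fitness_landscape(0.05, 0.1, 1e-5), 100, 0.1)
  expect_close(spv$rate1, 3.135e-8, 0.01)
})

test_that("tunneling success probability has the right closed form and limits", {
  expect_equal(
    tunneling_success_probability(fitness_landscape(0, 0.1, 1e-5),
                                  s_est = 0.1)$p1, 1e-3)
  expect_close(
    tunneling_success_probability(fitness_landscape(0.01, 0.1, 1e-5),
                                  s_est = 0.1)$p1, 9.901951e-5, 1e-6)
  expect_equal(
    tunneling_success_probability(fitness_landscape(0, 0.1, 0))$p1, 0)
  # deep valley asymptote mu * s_est / delta
  p_deep <- tunneling_success_probability(fitness_landscape(0.1, 0.2, 1e-8),
                                          s_est = 0.1)
  expect_close(p_deep$p1, 1e-8 * 0.1 / 0.1, 0.001)
  expect_identical(p_deep$regime, "deep-valley")
})

test_that("tunneling success probability matches a branching-process oracle", {
  # oracle: lineages with birth prob (1-delta)/(2-delta), success prob
  # mu*s_est per division; the closed form is an O(sqrt(mu s_est))
  # approximation, so the band is 3 SE plus a 2% linearisation allowance
  cases <- list(c(delta = 0, mu = 1e-4, s_est = 0.1),
                c(delta = 0.02, mu = 3e-4, s_est = 0.2))
  for (cs in cases) {
    p_closed <- tunneling_success_probability(
      fitness_landscape(cs[["delta"]], 0.5, cs[["mu"]]),
      s_est = cs[["s_est"]])$p1
    mc <- lineage_success_oracle(cs[["delta"]], cs[["mu"]], cs[["s_est"]],
                                 n_lineages = 2e5, seed = 71)
    expect_lt(abs(mc$p_success - p_closed),
              3 * mc$se + 0.02 * p_closed)
  }
})

test_that("tunneling prediction scales inversely with N and handles mu = 0", {
  ls <- fitness_landscape(0, 0.1, 1e-5)
  tp <- tunneling_prediction(ls, 1e5, 0.1, s_est = 0.1, supply_tol = Inf)
  expect_equal(tp$mean_time, 1e4)
  tp2 <- tunneling_prediction(ls, 2e5, 0.1, s_est = 0.1,
                              supply_tol = Inf)
  expect_equal(tp2$mean_time * 2, tp$mean_time)
  expect_error(
    tunneling_prediction(fitness_landscape(0, 0.1, 0), 100, 0.1),
    class = "invalid_parameter")
  expect_warning(tunneling_prediction(ls, 1e5, 0.1), "lineages may compete")
})

test_that("regime classification places the sequential/tunneling threshold", {
  ls <- fitness_landscape(0, 0.1, 1e-5)
  expect_identical(classify_regime(ls, 100, 0.1)$regime, "sequential")
  expect_identical(classify_regime(ls, 1e5, 0.1)$regime, "tunneling")
  thr <- classify_regime(ls, 100, 0.1)$N_threshold
  expect_true(thr > 100 && thr < 1e5)
  # at the threshold the two predictions agree
  sq <- sequential_prediction(ls, thr, 0.1)$mean_time
  tn <- tunneling_prediction(ls, thr, 0.1, supply_tol = Inf)$mean_time
  expect_close(sq, tn, 1e-6)
})

test_that("champion mean time: identities, quadrature, and MC oracle", {
  # D = 1 is the plain hypoexponential mean
  expect_equal(champion_mean_time(1e-6, 9.09e-6, 1), 1 / 1e-6 + 1 / 9.09e-6)
  # one-step regime: exponential order statistic 1/(D rate1)
  expect_close(champion_mean_time(1e-6, 1, 7), 1 / (7e-6), 1e-8)
  # quadrature against a Monte-Carlo minimum of hypoexponential draws
  set.seed(42)
  nmc <- 2e5
  draws <- matrix(rexp(7 * nmc, 1e-6) , nrow = 7) +
           matrix(rexp(7 * nmc, 9.09e-6), nrow = 7)
  mins <- apply(draws, 2, min)
  q <- champion_mean_time(1e-6, 9.09e-6, 7)
  expect_lt(abs(q - mean(mins)), 3 * sd(mins) / sqrt(nmc))
  # equal rates: stable branch
  expect_close(champion_mean_time(1e-3, 1e-3, 1), 2000, 1e-9)
  set.seed(43)
  draws2 <- matrix(rexp(3 * nmc, 1e-3) + rexp(3 * nmc, 1e-3), nrow = 3)
  mins2 <- apply(draws2, 2, min)
  q2 <- champion_mean_time(1e-3, 1.0000001e-3, 3)
  expect_lt(abs(q2 - mean(mins2)), 3 * sd(mins2) / sqrt(nmc))
})

test_that("champion time times D approaches 1/rate1 as rate2 dominates", {
  rate1 <- 1e-6
  for (D in c(2, 5, 20)) {
    cm <- champion_mean_time(rate1, rate1 * 1e4, D)
    expect_close(cm * D, 1 / rate1, 0.01)
  }
})

test_that("non-subdivided crossing time is the faster regime and monotone", {
  ls <- fitness_landscape(0, 0.1, 1e-5)
  deep_seq <- nonsubdivided_time(ls, 50, 0.1)
  expect_identical(deep_seq$regime, "sequential")
  expect_equal(deep_seq$mean_time, sequential_prediction(ls, 50, 0.1)$mean_time)
  deep_tun <- nonsubdivided_time(ls, 1e6, 0.1)
  expect_identical(deep_tun$regime, "tunneling")
  # plateau: tau(N_total) non-increasing in N_total
  Ns <- round(10^seq(1.2, 6, length.out = 12))
  taus <- vapply(Ns, function(n) nonsubdivided_time(ls, n, 0.1)$mean_time,
                 numeric(1))
  expect_true(all(diff(taus) <= 1e-9 * taus[-length(taus)]))
})
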