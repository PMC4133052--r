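test_that("deep-valley migration window reproduces the worked bounds", {
  ls <- fitness_landscape(0.05, 0.1, 1e-5)
  w <- migration_window(ls, N = 100, D = 10, g = 0.1, warn = FALSE)
  # frozen hand evaluation: upper = 2 g rho12 n_e / D, lower = 2 n_f g rho01
  expect_close(w$m_over_mu_max_approx, 0.271, 0.01)
  expect_close(w$m_over_mu_min_approx, 0.0176, 0.01)
  expect_close(w$ratio_approx, 15.4, 0.01)
  # general chain-based window stays within a few % of the simplified one
  expect_close(w$m_over_mu_max, w$m_over_mu_max_approx, 0.05)
  expect_close(w$m_over_mu_min, w$m_over_mu_min_approx, 0.05)
  expect_true(w$exists)
  expect_gt(w$ratio, 1)
})

test_that("window is flagged not applicable for a single deme", {
  w <- migration_window(fitness_landscape(0.05, 0.1, 1e-5), 100, 1, 0.1)
  expect_false(w$exists)
  expect_true(is.na(w$m_over_mu_min))
})

test_that("plateau window ratio grows with deme size", {
  ls <- fitness_landscape(0, 0.1, 1e-6)
  Rs <- vapply(c(30, 60, 120, 240),
               function(N) migration_window(ls, N, 8, 0.1,
                                            warn = FALSE)$ratio,
               numeric(1))
  expect_true(all(diff(Rs) > 0))
})

test_that("widest window is reached at the sequential-fixation threshold", {
  ls <- fitness_landscape(0, 0.1, 1e-8)
  rb <- window_ratio_bound(ls, D = 8, g = 0.1)
  expect_true(rb$N_threshold > 2)
  # R at the threshold exceeds R at half the threshold (monotone growth)
  w_half <- migration_window(ls, floor(rb$N_threshold / 2), 8, 0.1,
                             warn = FALSE)
  expect_gt(rb$R_max, w_half$ratio)
  # more demes -> narrower maximal window
  Rmax <- vapply(c(4, 8, 16, 32),
                 function(D) window_ratio_bound(ls, D, 0.1)$R_max,
                 numeric(1))
  expect_true(all(diff(Rmax) < 0))
  # orders-of-magnitude window at biological mutation rates
  rb_bio <- window_ratio_bound(fitness_landscape(0, 0.1, 1e-10), D = 96,
                               g = 0.1)
  expect_gt(rb_bio$R_max, 10)
})

test_that("speedup report encodes the necessary condition and closed forms", {
  # isolated demes tunneling: no speedup possible
  ls <- fitness_landscape(0, 0.1, 1e-3)
  sp_tun <- speedup_report(ls, N = 2000, D = 10, g = 0.1)
  expect_true(sp_tun$no_speedup)
  expect_gte(sp_tun$ratio_best_ideal, 1 - 1e-9)

  # sequential demes, tunneling non-subdivided population: ratio = p1/rho01 < 1
  ls2 <- fitness_landscape(0, 0.1, 1e-6)
  sp <- speedup_report(ls2, N = 100, D = 100, g = 0.1)
  expect_identical(sp$regime_deme, "sequential")
  expect_identical(sp$regime_nonsub, "tunneling")
  expect_lt(sp$ratio_closed_form, 1)
  expect_equal(sp$ratio_closed_form, sp$p1 / sp$rho01)
  expect_true(sp$necessary_condition)
  # plateau closed form N sqrt(mu s_est): matches the idealised tau ratio
  # within the p1-prefactor tolerance
  expect_close(sp$ratio_plateau_form, sp$ratio_best_ideal, 0.25)
  expect_lte(sp$tau_champion, sp$tau_deme)
})

test_that("p1 < rho01 whenever isolated demes fix sequentially", {
  set.seed(3)
  for (i in 1:20) {
    delta <- runif(1, 0, 0.1); mu <- 10^runif(1, -8, -4)
    ls <- fitness_landscape(delta, 0.1, mu)
    N <- sample(20:300, 1)
    if (classify_regime(ls, N, 0.1)$regime == "sequential") {
      p1 <- tunneling_success_probability(ls)$p1
      expect_lt(p1, fixation_probability(1, 1 - delta, N))
    }
  }
})

test_that("optimal valley depth sits at 2/N with the closed-form minimum", {
  od <- optimal_valley_depth(1e-5, 0.1, 100)
  expect_close(od$delta_star, 0.02, 1e-4)
  expect_close(od$ratio_min, exp(2) * 1e-5 * 0.1 * 100^2 / 4, 1e-6)
  # grid-search cross-check of the minimiser
  grid <- seq(0.001, 0.2, by = 1e-4)
  vals <- (1e-5 * 0.1 / grid^2) * exp(100 * grid)
  expect_close(grid[which.min(vals)], od$delta_star, 0.01)
  # ratio_min does not involve D
  expect_error(optimal_valley_depth(1e-5, 0.1, 5), class = "invalid_parameter")
})

test_that("island window: degenerate cases and plateau extinction probability", {
  ls <- fitness_landscape(0, 0.1, 1e-5)
  iw1 <- island_window(1000, 100, 1, ls, 0.1, warn = FALSE)
  expect_true(is.finite(iw1$m_over_mu_min) && is.finite(iw1$m_over_mu_max))
  expect_equal(iw1$rho_ext, 1 / 100)    # neutral: wild-type migrant fixes 1/N
  expect_error(island_window(100, 100, 3, ls, 0.1),
               class = "invalid_parameter")
  isc <- island_scenario()
  iw <- island_window(isc$N_large, isc$N_island, isc$C, isc$landscape, isc$g,
                      warn = FALSE)
  expect_true(iw$exists)
  expect_gt(iw$ratio, 10)
})

test_that("theory report serialises to stable JSON keys", {
  ls <- fitness_landscape(0.05, 0.1, 1e-5)
  rep <- theory_report(ls, deme_spec(K = 112, g = 0.1),
                       metapop_spec(D = 10, m = 2e-6))
  expect_setequal(names(rep),
                  c("version", "params", "validity_flags", "regimes", "rates",
                    "tau", "n_events", "window", "speedups", "delta_star"))
  js <- jsonlite::toJSON(unclass(rep), auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$window$ratio, rep$window$ratio, tolerance = 1e-12)
  expect_identical(back$regimes$deme, "sequential")
})
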