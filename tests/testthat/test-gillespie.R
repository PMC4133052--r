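test_that("simulation is deterministic given a seed, bit for bit", {
  ls <- plateau_landscape()
  dm <- deme_spec(K = 50, g = 0.1)
  mp <- metapop_spec(D = 3, m = 1e-4)
  a <- run_replicates(ls, dm, mp, n_replicates = 5, base_seed = 99,
                      t_max = 1e6)
  b <- run_replicates(ls, dm, mp, n_replicates = 5, base_seed = 99,
                      t_max = 1e6)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$summary, b$summary)
})

test_that("no mutation means no crossing; extinction is reported", {
  ls0 <- fitness_landscape(0, 0.1, 0)
  dm <- deme_spec(K = 30, g = 0.1)
  r <- simulate_crossing(ls0, dm, metapop_spec(D = 2, m = 0), seed = 1,
                         t_max = 200)
  expect_true(r$censored)
  expect_identical(r$status, "censored")
  # monomorphic closure: genotype composition never changes
  expect_equal(sum(r$final_counts[2:3, ]), 0)
})

test_that("migration conserves deme sizes and total genotype counts", {
  ls0 <- fitness_landscape(0, 0.1, 0)
  # demes exactly at carrying capacity with negligible death rate: the only
  # active events are migrations
  dm <- deme_spec(K = 40, g = 1e-9, N = 40)
  mp <- metapop_spec(D = 4, m = 0.5)
  init <- rbind(c(24L, 34L, 14L, 10L), c(10L, 0L, 20L, 0L), c(6L, 6L, 6L, 30L))
  r <- simulate_crossing(ls0, dm, mp, seed = 5, t_max = 50, init = init)
  expect_equal(colSums(r$final_counts), colSums(init))
  expect_equal(rowSums(r$final_counts), rowSums(init))
  expect_gt(r$counts[["migrations"]], 0)
})

test_that("occupancy fluctuates around the logistic equilibrium K(1 - g)", {
  dm <- deme_spec(K = 100, g = 0.1)
  oc <- occupancy_simulation(dm, D = 3, t_total = 4000, t_burnin = 400,
                             seed = 21)
  expect_close(oc$mean_total_size / 3, 90, 0.01)
})

test_that("single-deme crossing times match sequential-fixation theory", {
  ls <- plateau_landscape(mu = 1e-3)
  dm <- deme_spec(K = 50, g = 0.1)
  th <- sequential_prediction(ls, dm$N, dm$g)
  rr <- run_replicates(ls, dm, metapop_spec(D = 1, m = 0),
                       n_replicates = 150, base_seed = 11, t_max = 1e7)
  expect_equal(rr$summary$censored_n, 0)
  expect_lt(abs(rr$summary$mean - th$mean_time), 3.5 * rr$summary$se)
  # the 95% CI brackets its own mean
  expect_true(rr$summary$ci_low < rr$summary$mean &&
                rr$summary$mean < rr$summary$ci_high)
})

test_that("fixed-N scheme reduces to a Moran process at D = 1", {
  # a single genotype-2 invader among genotype-1 residents, no mutation:
  # fixation frequency must match the Moran closed form
  ls <- fitness_landscape(0, 0.3, 0)
  dm <- deme_spec(K = 34, g = 0.1, N = 30)
  mp <- metapop_spec(D = 1, m = 0)
  rho <- fixation_probability(1, 1.3, 30)
  set.seed(9); seeds <- sample.int(1e9, 500)
  fixed <- 0L
  for (sd in seeds) {
    r <- simulate_fixed_N(ls, dm, mp, seed = sd,
                          init = matrix(c(29L, 0L, 1L), 3, 1),
                          stop_when_monomorphic = TRUE)
    if (r$status == "crossed") fixed <- fixed + 1L
  }
  expect_lt(abs(fixed / 500 - rho), 3 * sqrt(rho * (1 - rho) / 500))
})

test_that("first deme to fix follows the champion order statistic", {
  ls <- plateau_landscape(mu = 1e-4)
  dm <- deme_spec(K = 50, g = 0.1)
  th <- sequential_prediction(ls, dm$N, dm$g)
  pred <- champion_mean_time(th$rate1, th$rate2, 7)
  rr <- run_replicates(ls, dm, metapop_spec(D = 7, m = 0),
                       n_replicates = 150, base_seed = 5, t_max = 1e8,
                       stop_at_first_fix = TRUE)
  ff <- rr$replicates$first_deme_fix_time
  expect_lt(abs(mean(ff) - pred), 3.5 * sd(ff) / sqrt(length(ff)))
})

test_that("replicate CI width shrinks like 1/sqrt(n)", {
  ls <- plateau_landscape(mu = 1e-3)
  dm <- deme_spec(K = 30, g = 0.1)
  mp <- metapop_spec(D = 1, m = 0)
  a <- run_replicates(ls, dm, mp, n_replicates = 60, base_seed = 2,
                      t_max = 1e7)
  b <- run_replicates(ls, dm, mp, n_replicates = 240, base_seed = 3,
                      t_max = 1e7)
  width_ratio <- (a$summary$ci_high - a$summary$ci_low) /
    (b$summary$ci_high - b$summary$ci_low)
  expect_gt(width_ratio, 1.3)   # expected 2, allow sampling noise
  expect_lt(width_ratio, 3.1)
})

test_that("a single-point sweep reproduces run_replicates and joins theory", {
  sc <- deep_valley_scenario()
  mp <- metapop_spec(D = sc$D, m = 0)
  tab <- sweep_crossing(sc$landscape, sc$deme, mp, axis = "m_over_mu",
                        grid = 0.03, n_replicates = 4, base_seed = 17,
                        t_max = 1e6)
  expect_identical(nrow(tab), 1L)
  set.seed(17); pseed <- sample.int(.Machine$integer.max - 1L, 1)
  mp2 <- metapop_spec(D = sc$D, m = 0.03 * sc$landscape$mu)
  ref <- run_replicates(sc$landscape, sc$deme, mp2, 4, base_seed = pseed,
                        t_max = 1e6)
  expect_equal(tab$mean, ref$summary$mean)
  w <- migration_window(sc$landscape, sc$deme$N, sc$D, sc$deme$g,
                        warn = FALSE)
  expect_equal(tab$theory_window_min, w$m_over_mu_min)
  expect_equal(tab$theory_window_max, w$m_over_mu_max)
  expect_false(tab$failed)
})
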