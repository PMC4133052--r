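# Shared study conditions for the stochastic checks. Parameters are scaled
# down relative to experimentally realistic mutation rates so that crossing
# times stay within CPU reach, while preserving the regime structure each
# check probes (see the methods vignette for the reasoning behind every
# value).

# plateau used for single-deme / champion checks
plateau_landscape <- function(mu = 1e-3) fitness_landscape(0, 0.1, mu)

# deep valley with a wide migration window (ratio ~ 34) and sequential
# demes at N = 24: delta * N = 4.8, sequential margin rho01/p1 ~ 3.4
deep_valley_scenario <- function() {
  list(landscape = fitness_landscape(delta = 0.2, s = 0.3, mu = 3e-4),
       deme = deme_spec(K = 27, g = 0.1),   # N = 24
       D = 4)
}

# hub-and-spoke: one large population coupled to C small valley-crossing
# islands; islands sequential, the large population tunnels slowly
island_scenario <- function() {
  list(landscape = fitness_landscape(delta = 0.2, s = 0.3, mu = 3e-4),
       N_large = 100, N_island = 24, C = 6, g = 0.1)
}

expect_close <- function(object, expected, tol, info = NULL) {
  expect_true(abs(object - expected) <= tol * abs(expected),
              info = paste0(info, ": got ", signif(object, 6), ", expected ",
                            signif(expected, 6), " (rel tol ", tol, ")"))
}
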