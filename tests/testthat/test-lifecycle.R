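test_that("environment schedule alternates in blocks of T from environment 1", {
  expect_equal(environment_at(c(0, 5, 1000), Inf), rep(1L, 3))
  expect_equal(environment_at(0:3, 1), c(1L, 2L, 1L, 2L))
  expect_equal(environment_at(c(9, 10, 19, 20), 10), c(1L, 2L, 2L, 1L))
  # period 2T
  g <- 0:50
  expect_equal(environment_at(g, 7), environment_at(g + 14, 7))
  expect_error(environment_at(0, 0), "positive")
  expect_error(environment_at(-1, 5), "non-negative")
})

test_that("viability selection is Bernoulli with probability = viability", {
  # all viability 1: everyone survives
  pop <- seeded_population(100, 0)
  out <- viability_selection(pop, 1, model_params(N = 100, S = 0))
  expect_equal(nrow(out), 100)
  expect_equal(attr(out, "mean_viability"), 1)

  # all viability 0: nobody survives
  pop_aa <- seeded_population(100, 200) # all aa
  out0 <- viability_selection(pop_aa, 1, model_params(N = 100, S = 1))
  expect_equal(nrow(out0), 0)

  # all viability 0.5 at N = 10^4: survivor count in the binomial 99.9% band
  set.seed(31)
  big <- seeded_population(1e4, 2e4)
  surv <- viability_selection(big, 1, model_params(N = 1e4, S = 0.5))
  band <- qbinom(c(5e-4, 1 - 5e-4), 1e4, 0.5)
  expect_gte(nrow(surv), band[1])
  expect_lte(nrow(surv), band[2])
})

test_that("mating transmits alleles Mendelian-independently", {
  # clonal case: AA/BB parents give AA/BB offspring
  par_fix <- seeded_population(5, 0)
  set.seed(32)
  kids <- mate(par_fix, 100)
  expect_true(all(kids$dosage_A == 2L) && all(kids$dosage_B == 2L))

  # Aa x Aa: dosages segregate 1:2:1
  par_het <- fixture_population("all_het", 2)
  set.seed(33)
  kids <- mate(par_het, 1e5)
  counts_A <- tabulate(kids$dosage_A + 1L, 3)
  expect_gt(chisq.test(counts_A, p = c(0.25, 0.5, 0.25))$p.value, 1e-3)

  # free recombination: locus A and B dosages independent in AaBb x AaBb
  expect_gt(chisq.test(table(kids$dosage_A, kids$dosage_B))$p.value, 1e-3)
})

test_that("reproduction failure is signalled with fewer than 2 parents", {
  lone <- seeded_population(2, 0)[1, ]
  expect_error(mate(lone, 10), class = "sgesim_extinction")
  pair <- seeded_population(2, 0)
  expect_error(mate(pair, 10, weights = c(1, 0)),
               class = "sgesim_extinction")
  expect_no_error(mate(pair, 10, weights = c(1, 0.5)))
})

test_that("fecundity weights are fitness relative to the population maximum", {
  # AA and Aa with S = 1, h1 = 0.5, no SGE: fitnesses 1.0 and 0.5
  pop <- tibble::tibble(dosage_A = c(2L, 1L), dosage_B = c(0L, 0L))
  p <- model_params(N = 2, S = 1, selection_mode = "symmetric_fecundity")
  expect_equal(fecundity_weights(pop, 1, p), c(1, 0.5))
  # equal fitness: all weights 1
  pop_eq <- seeded_population(5, 0, "bb")
  expect_equal(fecundity_weights(pop_eq, 1, model_params(N = 5, S = 0,
                 selection_mode = "symmetric_fecundity")), rep(1, 5))
})

test_that("one-generation step keeps N constant and records the summary", {
  p <- tiny_params(S = 0.4, sigma_BB = 0.5)
  set.seed(34)
  pop <- hwe_population(p$N, 0.5, 0.5)
  for (g in 0:4) {
    st <- step_generation(pop, g, p)
    expect_equal(nrow(st$population), p$N)
    s <- st$summary
    expect_true(s$freq_A >= 0 && s$freq_A <= 1)
    expect_true(s$exp_het_A <= 0.5 + 1e-12)
    expect_lte(s$n_survivors, p$N)
    expect_true(s$mean_viability >= 0 && s$mean_viability <= 1)
    pop <- st$population
  }
  # everyone viable: all N survive every generation
  st <- step_generation(seeded_population(20, 0), 0,
                        tiny_params(S = 0, sigma_BB = 0))
  expect_equal(st$summary$n_survivors, 20)
})

test_that("population-wide death raises the extinction condition", {
  pop_aa <- seeded_population(20, 40) # all aa, lethal in environment 1
  p <- tiny_params(S = 1, sigma_BB = 0)
  expect_error(step_generation(pop_aa, 0, p), class = "sgesim_extinction")
  traj <- simulate_trajectory(p, init = hwe_population(20, 0, 0.5), seed = 5)
  expect_true(attr(traj, "extinct"))
  expect_equal(nrow(traj), 1)
})

test_that("fixation and loss are absorbing at each locus", {
  # start monomorphic AA/bb; no mutation, so it must stay monomorphic
  p <- tiny_params(S = 0.5, sigma_BB = 1, n_generations = 30)
  traj <- simulate_trajectory(p, init = seeded_population(p$N, 0, "bb"),
                              seed = 6)
  expect_true(all(traj$freq_A == 1))
  expect_true(all(traj$freq_B == 0))
})

test_that("trajectories are bit-identical under the same seed", {
  p <- tiny_params(N = 2, S = 0.3, sigma_BB = 0.5, n_generations = 20)
  run_a <- simulate_trajectory(p, seed = 99)
  run_b <- simulate_trajectory(p, seed = 99)
  expect_identical(as.data.frame(run_a), as.data.frame(run_b))
  p2 <- model_params(N = 200, S = 0.5, sigma_BB = 1, t_switch = 3,
                     n_generations = 25)
  run_c <- simulate_trajectory(p2, seed = 100)
  run_d <- simulate_trajectory(p2, seed = 100)
  expect_identical(as.data.frame(run_c), as.data.frame(run_d))
})

test_that("with no selection and no SGE the mean frequency change is drift", {
  # over replicates, the mean per-generation frequency change is ~ 0
  p <- model_params(N = 50, S = 0, sigma_BB = 0, n_generations = 20,
                    n_replicates = 200, seed = 7)
  deltas <- vapply(seq_len(p$n_replicates), function(r) {
    traj <- simulate_trajectory(p, seed = derive_seed(p$seed, r))
    traj$freq_A[nrow(traj)] - traj$freq_A[1]
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3.5 * se + 1e-8)
})
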