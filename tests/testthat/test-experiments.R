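test_that("exact oracle reproduces the neutral martingale", {
  for (N in 2:4) {
    orc <- markov_oracle(N, S = 0, sigma = 0)
    expect_equal(orc$p_fix_a, (0:(2 * N)) / (2 * N))
    expect_equal(orc$p_extinct, rep(0, 2 * N + 1))
  }
})

test_that("oracle rows are proper probability decompositions", {
  for (S in c(0.3, 0.8)) {
    for (sig in c(0, 0.5)) {
      orc <- markov_oracle(3, S = S, sigma = sig)
      expect_true(all(orc$p_fix_a >= 0 & orc$p_fix_a <= 1))
      expect_true(all(orc$p_loss_a >= -1e-12))
      expect_equal(orc$p_fix_a + orc$p_loss_a + orc$p_extinct,
                   rep(1, nrow(orc)))
    }
  }
  expect_error(markov_oracle(5), "N <= 4")
})

test_that("Monte-Carlo fixation agrees with the exact oracle", {
  # one selected, one noisy cell; the full 3x3 grid runs in the
  # acceptance suite
  nrep <- 3000
  for (cell in list(list(S = 0.5, sig = 0), list(S = 0.2, sig = 1))) {
    p <- model_params(N = 3, S = cell$S, sigma_BB = cell$sig,
                      n_replicates = nrep, seed = 101)
    res <- run_fixation_experiment(p, n_copies_a = 1)
    orc <- markov_oracle(3, S = cell$S, sigma = cell$sig)
    expected <- orc$p_fix_given_surviving[orc$initial_copies_a == 1]
    se <- prop_se(expected, res$n_informative)
    expect_lt(abs(res$fixation_probability - expected), 3 * se + 1e-9)
  }
})

test_that("a lethal recessive allele starting from one copy never fixes", {
  p <- model_params(N = 30, S = 1, sigma_BB = 0, n_replicates = 300,
                    seed = 102)
  res <- run_fixation_experiment(p)
  expect_equal(res$n_fixed, 0)
  expect_equal(res$relative_fixation, 0)
})

test_that("meta-replication attaches a standard deviation", {
  p <- model_params(N = 10, S = 0, sigma_BB = 0, n_replicates = 200,
                    seed = 103)
  res <- run_fixation_experiment(p, n_meta = 4)
  expect_equal(nrow(tidy(res)), 800)
  expect_false(is.na(res$sd_fixation))
  g <- glance(res)
  expect_equal(g$n_meta, 4)
  # aggregate equals the mean over per-replicate outcomes
  expect_equal(res$fixation_probability,
               with(tidy(res), sum(outcome == "fixed") /
                                 sum(outcome %in% c("fixed", "lost"))))
})

test_that("an effect-free modifier locus drifts around frequency 0.5", {
  p <- model_params(N = 100, S = 0.5, sigma_BB = 0, n_generations = 100,
                    n_replicates = 60, seed = 104)
  res <- run_modifier_experiment(p)
  expect_lt(abs(res$mean_final_freq_B - 0.5), 3 * res$se_final_freq_B)
  expect_equal(res$n_extinct, 0)
})

test_that("modifier driver supports the fixed-A and fixed-a starts", {
  p <- model_params(N = 40, S = 0.8, sigma_BB = 1, t_switch = 5,
                    n_generations = 30, n_replicates = 10, seed = 105)
  res_A <- run_modifier_experiment(p, init = "fixed_A",
                                   record_trajectories = TRUE)
  expect_equal(res_A$trajectories$freq_A[res_A$trajectories$generation == 0],
               rep(1, 10))
  res_a <- run_modifier_experiment(p, init = "fixed_a",
                                   record_trajectories = TRUE)
  expect_equal(res_a$trajectories$freq_A[res_a$trajectories$generation == 0],
               rep(0, 10))
})

test_that("early stopping leaves final frequencies unchanged", {
  p <- model_params(N = 30, S = 0.9, sigma_BB = 1, n_generations = 200,
                    n_replicates = 20, seed = 106)
  fast <- run_modifier_experiment(p, early_stop = TRUE)
  slow <- run_modifier_experiment(p, early_stop = FALSE)
  both_ok <- !fast$replicates$extinct & !slow$replicates$extinct
  expect_equal(fast$replicates$final_freq_B[both_ok],
               slow$replicates$final_freq_B[both_ok])
})

test_that("sweeps are deterministic, cell-seeded, and reject bad grids", {
  base <- model_params(N = 30, n_generations = 15, n_replicates = 5,
                       seed = 107)
  grid <- tidyr::expand_grid(S = c(0.2, 0.8), sigma_BB = c(0, 1))
  sw <- run_sweep(grid, "modifier", base)
  expect_equal(nrow(sw), 4)
  sw2 <- run_sweep(grid, "modifier", base)
  expect_equal(as.data.frame(sw), as.data.frame(sw2))

  # 1-cell grid reproduces a direct driver call with the derived seed
  one <- run_sweep(grid[2, ], "modifier", base)
  direct <- run_modifier_experiment(
    model_params(N = 30, S = grid$S[2], sigma_BB = grid$sigma_BB[2],
                 n_generations = 15, n_replicates = 5,
                 seed = derive_seed(107, 1, stream = 69621)))
  expect_equal(one$mean_final_freq_B, direct$mean_final_freq_B)

  expect_error(run_sweep(grid[c(1, 1), ], "modifier", base), "duplicated")
  expect_error(run_sweep(tibble::tibble(S = 0.1, bogus = 2), "modifier",
                         base), "bogus")
  expect_error(run_sweep(grid[0, ], "modifier", base), "nonempty")
})

test_that("fixation sweeps carry relative fixation per cell", {
  base <- model_params(N = 10, n_replicates = 50, seed = 108)
  sw <- run_sweep(tidyr::expand_grid(S = c(0, 0.5)), "fixation", base)
  expect_true(all(c("fixation_probability", "relative_fixation") %in%
                    names(sw)))
  expect_true(all(sw$relative_fixation >= 0))
})

test_that("dominance preset grid covers all h combinations at N = 1000", {
  g <- dominance_grid(S = 0.9, sigma_BB = 1, t_switch = 1)
  expect_equal(nrow(g), 27)
  expect_true(all(g$N == 1000))
  expect_equal(sort(unique(g$hb)), c(0, 0.5, 1))
})

test_that("tidiers and plots expose the result contents", {
  p <- model_params(N = 20, S = 0.5, sigma_BB = 0.5, n_generations = 10,
                    n_replicates = 8, seed = 109)
  res <- run_modifier_experiment(p)
  expect_equal(nrow(tidy(res)), 8)
  expect_equal(nrow(glance(res)), 1)
  expect_s3_class(autoplot(res), "ggplot")
  resf <- run_fixation_experiment(model_params(N = 10, n_replicates = 20,
                                               seed = 110))
  expect_s3_class(autoplot(resf), "ggplot")
  traj <- simulate_trajectory(p)
  expect_s3_class(autoplot(traj), "ggplot")
  sw <- run_sweep(tidyr::expand_grid(S = c(0.1, 0.9), sigma_BB = c(0, 1)),
                  "modifier", p)
  expect_s3_class(autoplot(sw), "ggplot")
})
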