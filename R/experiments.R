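#' Fixation-probability experiment for a deleterious allele
#'
#' Seeds `n_copies_a` copies of the deleterious allele `a` (default one
#' copy, frequency `1/2N`) into an otherwise `AA` population with the
#' modifier locus monomorphic (default `BB`, so the SGE magnitude is the
#' constant `sigma_BB`), and runs each replicate under the stable (or
#' scheduled) environment until locus A is absorbed — allele `a` fixed or
#' lost. Reports the fixation probability and its value relative to the
#' neutral expectation (the initial frequency `n_copies_a / 2N`).
#'
#' @param params An [model_params()] object; `n_replicates` replicates are
#'   run per meta-replicate.
#' @param n_copies_a Initial copies of allele `a` (default 1).
#' @param genotype_B Uniform modifier genotype (`"BB"`, `"Bb"`, `"bb"`).
#' @param n_meta Outer meta-replicates: the whole experiment is repeated
#'   `n_meta` times (with independent derived seeds) to attach a standard
#'   deviation to the fixation probability. Default 1.
#' @param max_generations Safety cap per replicate; replicates still
#'   polymorphic at the cap are flagged `"censored"` and excluded, like
#'   extinct ones, from the probability.
#' @return An object of class `sge_fixation_result`. Use [tidy()] for the
#'   per-replicate table and [glance()] for the one-row summary.
#' @examples
#' p <- model_params(N = 20, S = 0, sigma_BB = 0, n_replicates = 200)
#' glance(run_fixation_experiment(p))
#' @export
run_fixation_experiment <- function(params, n_copies_a = 1,
                                    genotype_B = "BB", n_meta = 1,
                                    max_generations = 1e6) {
  check_count(n_meta, "n_meta", min = 1)
  init <- seeded_population(params$N, n_copies_a, genotype_B)
  dA0 <- init$dosage_A
  dB0 <- init$dosage_B
  twoN <- 2L * params$N
  init_freq <- n_copies_a / twoN

  reps <- vector("list", n_meta)
  for (m in seq_len(n_meta)) {
    outcome <- character(params$n_replicates)
    gens <- integer(params$n_replicates)
    for (r in seq_len(params$n_replicates)) {
      set.seed(derive_seed(params$seed, (m - 1L) * params$n_replicates + r))
      dA <- dA0
      dB <- dB0
      g <- 0L
      res <- "censored"
      while (g < max_generations) {
        ca <- twoN - sum(dA)
        if (ca == 0L) { res <- "lost"; break }
        if (ca == twoN) { res <- "fixed"; break }
        st <- step_raw(dA, dB, g, params)
        if (st$extinct) { res <- "extinct"; break }
        dA <- st$dA
        dB <- st$dB
        g <- g + 1L
      }
      outcome[r] <- res
      gens[r] <- g
    }
    reps[[m]] <- tibble(meta = m, replicate = seq_along(outcome),
                        outcome = outcome, generations = gens)
  }
  reps <- dplyr::bind_rows(reps)

  per_meta <- reps |>
    dplyr::group_by(.data$meta) |>
    dplyr::summarise(
      n_informative = sum(.data$outcome %in% c("fixed", "lost")),
      n_fixed = sum(.data$outcome == "fixed"),
      .groups = "drop") |>
    dplyr::mutate(p_fix = .data$n_fixed / .data$n_informative)
  n_inf <- sum(per_meta$n_informative)
  p_fix <- sum(reps$outcome == "fixed") / n_inf

  structure(
    list(params = params, n_copies_a = n_copies_a, genotype_B = genotype_B,
         n_meta = n_meta, replicates = reps,
         n_fixed = sum(reps$outcome == "fixed"),
         n_lost = sum(reps$outcome == "lost"),
         n_extinct = sum(reps$outcome == "extinct"),
         n_censored = sum(reps$outcome == "censored"),
         n_informative = n_inf,
         initial_frequency = init_freq,
         fixation_probability = p_fix,
         sd_fixation = if (n_meta > 1) sd(per_meta$p_fix) else NA_real_,
         relative_fixation = p_fix / init_freq),
    class = "sge_fixation_result")
}

#' Modifier-allele experiment over a fixed horizon
#'
#' Tracks the SGE-enhancing allele `B` for `params$n_generations`
#' generations (the advantage call of the study design: enhanced SGE is
#' advantageous if the replicate-averaged final frequency of `B` exceeds
#' its initial value 0.5). The default initial condition is Hardy-Weinberg
#' proportions at frequency 0.5 at both loci; `init = "fixed_A"` starts
#' locus A monomorphic for the locally adaptive allele `A` (and
#' `"fixed_a"` for `a`), with locus B still at Hardy-Weinberg 0.5.
#'
#' @param params An [model_params()] object.
#' @param init `"hwe"`, `"fixed_A"` or `"fixed_a"`.
#' @param record_trajectories If `TRUE`, keep every replicate's
#'   per-generation summary (disables early stopping).
#' @param early_stop When both loci are monomorphic the allele-frequency
#'   state can no longer change, so the remaining generations are skipped
#'   and the current frequencies carried to the horizon. Disable to
#'   simulate every generation (the skipped tail's residual extinction
#'   risk is the only difference; it is negligible away from lethal
#'   parameter corners).
#' @return An object of class `sge_modifier_result`; see [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' p <- model_params(N = 50, S = 0.9, sigma_BB = 1, n_generations = 50,
#'                   n_replicates = 20)
#' glance(run_modifier_experiment(p))
#' @export
run_modifier_experiment <- function(params,
                                    init = c("hwe", "fixed_A", "fixed_a"),
                                    record_trajectories = FALSE,
                                    early_stop = !record_trajectories) {
  init <- match.arg(init)
  nrep <- params$n_replicates
  ngen <- params$n_generations
  final_A <- final_B <- rep(NA_real_, nrep)
  extinct <- logical(nrep)
  gens_run <- integer(nrep)
  trajs <- if (record_trajectories) vector("list", nrep) else NULL
  n_neg_total <- 0L

  for (r in seq_len(nrep)) {
    set.seed(derive_seed(params$seed, r))
    dA <- switch(init,
                 hwe = rbinom(params$N, 2L, 0.5),
                 fixed_A = rep(2L, params$N),
                 fixed_a = rep(0L, params$N))
    dB <- rbinom(params$N, 2L, 0.5)
    rows <- if (record_trajectories) vector("list", ngen) else NULL
    died <- FALSE
    g <- 0L
    while (g < ngen) {
      if (early_stop && all(dA == dA[1L]) && all(dB == dB[1L])) break
      st <- step_raw(dA, dB, g, params)
      if (record_trajectories) {
        rows[[g + 1L]] <- population_summary(dA, dB, g, st$env,
                                             st$n_survivors,
                                             st$mean_viability)
      }
      n_neg_total <- n_neg_total + st$n_neg
      if (st$extinct) { died <- TRUE; break }
      dA <- st$dA
      dB <- st$dB
      g <- g + 1L
    }
    extinct[r] <- died
    gens_run[r] <- g
    if (!died) {
      final_A[r] <- sum(dA) / (2 * params$N)
      final_B[r] <- sum(dB) / (2 * params$N)
    }
    if (record_trajectories) {
      trajs[[r]] <- dplyr::bind_rows(rows[!vapply(rows, is.null, TRUE)]) |>
        dplyr::mutate(replicate = r, .before = 1)
    }
  }
  if (n_neg_total > 0L) {
    warn(sprintf("%d fitness values below 0 truncated in symmetric mode.",
                 n_neg_total))
  }

  ok <- !extinct
  mean_B <- mean(final_B[ok])
  se_B <- if (sum(ok) > 1) sd(final_B[ok]) / sqrt(sum(ok)) else NA_real_
  structure(
    list(params = params, init = init,
         replicates = tibble(replicate = seq_len(nrep),
                             final_freq_A = final_A,
                             final_freq_B = final_B,
                             extinct = extinct,
                             generations_run = gens_run),
         trajectories = if (record_trajectories) dplyr::bind_rows(trajs)
                        else NULL,
         n_extinct = sum(extinct),
         mean_final_freq_B = mean_B,
         se_final_freq_B = se_B,
         mean_final_freq_A = mean(final_A[ok]),
         advantage = isTRUE(mean_B > 0.5)),
    class = "sge_modifier_result")
}

#' Run an experiment over a parameter grid
#'
#' Takes a tibble with one row per parameter combination (columns are any
#' subset of `N`, `S`, `h1`, `h2`, `hb`, `sigma_BB`, `t_switch`,
#' `selection_mode`, `n_generations`, `n_replicates`, plus the
#' driver-specific `init` or `n_copies_a`) and runs one experiment per
#' cell, with a per-cell seed derived from `base_params$seed` and the cell
#' index so cells are independent and individually reproducible. Cell
#' ordering is the row order of `grid`.
#'
#' @param grid Tibble of parameter combinations; duplicated rows are an
#'   error.
#' @param kind `"modifier"` or `"fixation"`.
#' @param base_params Defaults for columns absent from `grid`.
#' @param on_cell Optional callback `function(row, i)` invoked with each
#'   finished cell's result row (used e.g. to flush partial sweep results
#'   to disk).
#' @param ... Passed to the underlying driver.
#' @return A tibble of class `sge_sweep`: the grid columns plus the
#'   per-cell aggregates (`mean_final_freq_B`, `se_final_freq_B`,
#'   `advantage`, `n_extinct` for modifier runs; `fixation_probability`,
#'   `relative_fixation`, `n_informative` for fixation runs) and the cell
#'   seed.
#' @examples
#' grid <- tidyr::expand_grid(S = c(0, 0.9), sigma_BB = c(0, 1))
#' run_sweep(grid, "modifier",
#'           model_params(N = 30, n_generations = 20, n_replicates = 5))
#' @export
run_sweep <- function(grid, kind = c("modifier", "fixation"),
                      base_params = model_params(), on_cell = NULL, ...) {
  kind <- match.arg(kind)
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    abort("`grid` must be a nonempty data frame of parameter combinations.")
  }
  if (anyDuplicated(grid)) abort("`grid` contains duplicated cells.")
  param_cols <- intersect(names(grid),
                          c("N", "S", "h1", "h2", "hb", "sigma_BB",
                            "t_switch", "selection_mode", "n_generations",
                            "n_replicates"))
  extra_cols <- setdiff(names(grid), c(param_cols, "init", "n_copies_a"))
  if (length(extra_cols)) {
    abort(sprintf("Unknown grid column(s): %s.",
                  paste(extra_cols, collapse = ", ")))
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, param_cols, drop = FALSE])
    cell_seed <- derive_seed(base_params$seed, i, stream = 69621)
    par <- do.call(model_params,
                   modifyList(unclass(base_params)[setdiff(names(unclass(base_params)), "seed")],
                              c(cell, list(seed = cell_seed))))
    if (kind == "modifier") {
      init <- if ("init" %in% names(grid)) grid$init[i] else "hwe"
      res <- run_modifier_experiment(par, init = init, ...)
      rows[[i]] <- dplyr::bind_cols(
        grid[i, , drop = FALSE],
        tibble(cell_seed = cell_seed,
               n_replicates_run = par$n_replicates,
               mean_final_freq_B = res$mean_final_freq_B,
               se_final_freq_B = res$se_final_freq_B,
               advantage = res$advantage,
               n_extinct = res$n_extinct))
    } else {
      k <- if ("n_copies_a" %in% names(grid)) grid$n_copies_a[i] else 1
      res <- run_fixation_experiment(par, n_copies_a = k, ...)
      rows[[i]] <- dplyr::bind_cols(
        grid[i, , drop = FALSE],
        tibble(cell_seed = cell_seed,
               n_replicates_run = par$n_replicates,
               fixation_probability = res$fixation_probability,
               relative_fixation = res$relative_fixation,
               n_informative = res$n_informative,
               n_extinct = res$n_extinct))
    }
    if (!is.null(on_cell)) on_cell(rows[[i]], i)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sge_sweep", class(out))
  attr(out, "kind") <- kind
  attr(out, "base_params") <- base_params
  out
}

#' Preset dominance sweep grid
#'
#' The dominance study design: every combination of `h1`, `h2`, `hb` in
#' \{0, 0.5, 1\} at `N = 1000`, crossed with the supplied selection
#' strengths, SGE magnitudes and switch intervals.
#'
#' @param S,sigma_BB,t_switch Grid axes.
#' @return A tibble usable as the `grid` of [run_sweep()].
#' @export
dominance_grid <- function(S = c(0.7, 0.8, 0.9), sigma_BB = c(0.1, 1),
                           t_switch = c(1, 10, 100)) {
  tidyr::expand_grid(N = 1000L, h1 = c(0, 0.5, 1), h2 = c(0, 0.5, 1),
                     hb = c(0, 0.5, 1), S = S, sigma_BB = sigma_BB,
                     t_switch = t_switch)
}

#' Exact absorption probabilities for small populations
#'
#' Builds the full Markov chain of this life cycle on genotype-count
#' states (n_AA, n_Aa, n_aa) for a population of size `N` at most 4, under
#' stable environment 1 with a constant SGE magnitude `sigma` (the
#' modifier locus monomorphic), and solves the linear system for the exact
#' probability that allele `a` fixes, is lost, or the population goes
#' extinct (fewer than 2 survivors), from every initial copy number of
#' `a`. Survival probabilities integrate the Gaussian perturbation through
#' [expected_clamped_viability()]; mating uses the exact ordered
#' distinct-pair probabilities and multinomial offspring counts. This is
#' the independent oracle against which the Monte-Carlo drivers are
#' validated.
#'
#' @param N Population size, 2 to 4.
#' @param S Selection coefficient.
#' @param sigma Constant SGE standard deviation.
#' @param h1 Dominance degree (environment 1).
#' @return A tibble with one row per initial copy number `0..2N`:
#'   `initial_copies_a`, `p_fix_a`, `p_loss_a`, `p_extinct`, and
#'   `p_fix_given_surviving` (fixation probability conditional on the
#'   replicate not going extinct, the quantity the fixation driver
#'   estimates).
#' @examples
#' markov_oracle(2, S = 0, sigma = 0)   # neutral: p_fix_a = k / 4
#' @export
markov_oracle <- function(N, S = 0, sigma = 0, h1 = 0.5) {
  check_count(N, "N", min = 2)
  if (N > 4) abort("Exact oracle is limited to N <= 4 (state space growth).")
  check_unit_interval(S, "S")
  if (sigma < 0) abort("`sigma` must be non-negative.")

  # states: genotype counts (n_AA, n_Aa, n_aa) summing to N
  states <- tidyr::expand_grid(n_AA = 0:N, n_Aa = 0:N) |>
    dplyr::mutate(n_aa = N - .data$n_AA - .data$n_Aa) |>
    dplyr::filter(.data$n_aa >= 0)
  ns <- nrow(states)
  a_copies <- states$n_Aa + 2L * states$n_aa
  fix_i <- which(a_copies == 2L * N)
  loss_i <- which(a_copies == 0L)
  transient <- setdiff(seq_len(ns), c(fix_i, loss_i))

  # per-genotype survival probability (genotype order: AA, Aa, aa)
  surv <- expected_clamped_viability(c(1, 1 - h1 * S, 1 - S), sigma)
  tA <- c(1, 0.5, 0) # P(transmit allele A | genotype)

  smat <- as.matrix(states[, c("n_AA", "n_Aa", "n_aa")])
  M <- matrix(0, ns, ns)
  p_ext_step <- numeric(ns)
  for (si in transient) {
    cnt <- smat[si, ]
    for (sAA in 0:cnt[1]) for (sAa in 0:cnt[2]) for (saa in 0:cnt[3]) {
      pr <- dbinom(sAA, cnt[1], surv[1]) * dbinom(sAa, cnt[2], surv[2]) *
        dbinom(saa, cnt[3], surv[3])
      if (pr == 0) next
      s <- c(sAA, sAa, saa)
      tot <- sum(s)
      if (tot < 2L) {
        p_ext_step[si] <- p_ext_step[si] + pr
        next
      }
      # child dosage distribution over ordered distinct parent pairs
      s1 <- sum(s * tA); s2 <- sum(s * tA^2)
      u1 <- sum(s * (1 - tA)); u2 <- sum(s * (1 - tA)^2)
      denom <- tot * (tot - 1)
      pAA <- (s1^2 - s2) / denom
      paa <- (u1^2 - u2) / denom
      pvec <- c(pAA, max(0, 1 - pAA - paa), paa) # order AA, Aa, aa
      for (sj in seq_len(ns)) {
        M[si, sj] <- M[si, sj] + pr * dmultinom(smat[sj, ], N, pvec)
      }
    }
  }

  # absorption probabilities from transient states
  Q <- M[transient, transient, drop = FALSE]
  I <- diag(length(transient))
  r_fix <- rowSums(M[transient, fix_i, drop = FALSE])
  fundamental <- solve(I - Q)
  f_fix <- as.vector(fundamental %*% r_fix)
  f_ext <- as.vector(fundamental %*% p_ext_step[transient])

  p_fix <- p_ext <- numeric(ns)
  p_fix[fix_i] <- 1
  p_fix[transient] <- f_fix
  p_ext[transient] <- f_ext

  # map each initial copy number to its seeded-population state
  k <- 0:(2L * N)
  n_aa0 <- pmax(0L, k - N)
  n_Aa0 <- k - 2L * n_aa0
  idx <- match(paste(N - n_Aa0 - n_aa0, n_Aa0, n_aa0),
               paste(states$n_AA, states$n_Aa, states$n_aa))
  tibble(initial_copies_a = k,
         p_fix_a = p_fix[idx],
         p_extinct = p_ext[idx],
         p_loss_a = 1 - p_fix[idx] - p_ext[idx],
         p_fix_given_surviving = p_fix[idx] / (1 - p_ext[idx]))
}
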