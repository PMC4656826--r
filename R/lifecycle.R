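#' Environment at a given generation
#'
#' Two environments alternate every `t_switch` generations. Generations are
#' 0-indexed and the initial environment is 1, so environment blocks are
#' `[0, T)`, `[T, 2T)`, ...: environment 1 when `floor(g / T)` is even,
#' environment 2 when it is odd. `t_switch = Inf` is the permanently stable
#' environment 1.
#'
#' @param generation Non-negative generation index (vectorized).
#' @param t_switch Switch interval in generations (positive, possibly Inf).
#' @return Integer vector of environment labels (1 or 2).
#' @examples
#' environment_at(0:5, t_switch = 2)   # 1 1 2 2 1 1
#' @export
environment_at <- function(generation, t_switch) {
  if (!is.numeric(t_switch) || length(t_switch) != 1L || is.na(t_switch) ||
      t_switch <= 0) {
    abort("`t_switch` must be a positive number of generations (or Inf).")
  }
  if (any(generation < 0)) abort("`generation` must be non-negative.")
  if (is.infinite(t_switch)) return(rep(1L, length(generation)))
  ifelse(floor(generation / t_switch) %% 2 == 0, 1L, 2L)
}

## draw N ordered pairs of DISTINCT parent indices in 1..ns;
## uniform when weights is NULL, else proportional to weights
sample_pairs <- function(ns, N, weights = NULL) {
  if (is.null(weights)) {
    p1 <- sample.int(ns, N, replace = TRUE)
    p2 <- sample.int(ns, N, replace = TRUE)
  } else {
    cw <- cumsum(weights)
    tot <- cw[ns]
    p1 <- findInterval(runif(N) * tot, cw) + 1L
    p2 <- findInterval(runif(N) * tot, cw) + 1L
  }
  tries <- 0L
  while (any(clash <- p1 == p2)) {
    n2 <- sum(clash)
    p2[clash] <- if (is.null(weights)) {
      sample.int(ns, n2, replace = TRUE)
    } else {
      findInterval(runif(n2) * tot, cw) + 1L
    }
    tries <- tries + 1L
    if (tries > 10000L) abort("Could not draw distinct mating pairs.")
  }
  list(p1 = p1, p2 = p2)
}

#' Viability selection on a population
#'
#' Each individual draws one SGE perturbation, its viability is clamped
#' into `[0, 1]`, and it survives an independent Bernoulli trial with
#' success probability equal to that realized viability. Survivors retain
#' their genotypes.
#'
#' @param pop Population tibble.
#' @param env Environment label (1 or 2).
#' @param params An [model_params()] object (absorbing-viability mode).
#' @return The survivor population tibble, with attributes `n_survivors`
#'   and `mean_viability` (mean realized viability of the pre-selection
#'   population).
#' @export
viability_selection <- function(pop, env, params) {
  validate_population(pop)
  base <- base_viability(pop$dosage_A, env, params$S, params$h1, params$h2)
  sig <- sge_sigma(pop$dosage_B, params$sigma_BB, params$hb)
  w <- realized_viability(base, draw_sge(sig), "absorbing_viability")
  alive <- runif(nrow(pop)) < w
  out <- pop[alive, ]
  attr(out, "n_survivors") <- sum(alive)
  attr(out, "mean_viability") <- mean(w)
  out
}

#' Fecundity weights under the symmetric selection mode
#'
#' In the symmetric mode the upper fitness boundary is removed and nobody
#' dies; instead each individual's mating probability is its fitness
#' relative to the highest fitness in the population, a weight in
#' `[0, 1]`.
#'
#' @inheritParams viability_selection
#' @return Numeric vector of per-individual weights in `[0, 1]`.
#' @export
fecundity_weights <- function(pop, env, params) {
  validate_population(pop)
  base <- base_viability(pop$dosage_A, env, params$S, params$h1, params$h2)
  sig <- sge_sigma(pop$dosage_B, params$sigma_BB, params$hb)
  w <- realized_viability(base, draw_sge(sig), "symmetric_fecundity")
  mx <- max(w)
  if (mx <= 0) abort("Degenerate population: maximum fitness is not positive.",
                     class = "sgesim_extinction")
  w / mx
}

#' Random mating with Mendelian transmission
#'
#' Produces exactly `N` offspring. For each offspring two distinct parents
#' are drawn (uniformly among survivors, or with probability proportional
#' to `weights`), redrawn independently across offspring, so one
#' individual may parent many offspring but each mating event yields one
#' offspring. At each locus independently the offspring receives one
#' uniformly chosen allele from each parent's dosage — free recombination
#' is exactly independent Mendelian transmission at the two loci.
#'
#' @param parents Survivor population tibble (at least 2 rows; with
#'   `weights`, at least 2 positive weights).
#' @param N Number of offspring to produce.
#' @param weights Optional per-parent mating weights (fecundity mode).
#' @return Offspring population tibble with exactly `N` rows.
#' @export
mate <- function(parents, N, weights = NULL) {
  validate_population(parents, "parents")
  check_count(N, "N", min = 1)
  ns <- nrow(parents)
  if (!is.null(weights)) {
    if (length(weights) != ns || any(weights < 0)) {
      abort("`weights` must be non-negative, one per parent.")
    }
    if (sum(weights > 0) < 2L) {
      abort("Fewer than 2 parents with positive mating weight.",
            class = "sgesim_extinction")
    }
  } else if (ns < 2L) {
    abort("Fewer than 2 surviving parents.", class = "sgesim_extinction")
  }
  pr <- sample_pairs(ns, N, weights)
  dA <- parents$dosage_A
  dB <- parents$dosage_B
  new_population(
    (runif(N) < dA[pr$p1] / 2) + (runif(N) < dA[pr$p2] / 2),
    (runif(N) < dB[pr$p1] / 2) + (runif(N) < dB[pr$p2] / 2)
  )
}

## fast one-generation step on raw dosage vectors; returns NULL components
## on reproduction failure (< 2 eligible parents)
step_raw <- function(dA, dB, generation, par) {
  N <- length(dA)
  env <- if (is.infinite(par$t_switch)) 1L
         else if (floor(generation / par$t_switch) %% 2 == 0) 1L else 2L
  base <- if (env == 1L) c(1 - par$S, 1 - par$h1 * par$S, 1)[dA + 1L]
          else c(1, 1 - par$h2 * par$S, 1 - par$S)[dA + 1L]
  sig <- c(0, par$hb, 1)[dB + 1L] * par$sigma_BB
  q <- rnorm(N, 0, sig)
  n_neg <- 0L
  if (par$selection_mode == "absorbing_viability") {
    w <- pmin(pmax(base + q, 0), 1)
    alive <- runif(N) < w
    ns <- sum(alive)
    if (ns < 2L) {
      return(list(extinct = TRUE, env = env, n_survivors = ns,
                  mean_viability = mean(w), n_neg = 0L))
    }
    idx <- which(alive)
    pr <- sample_pairs(ns, N)
    p1 <- idx[pr$p1]
    p2 <- idx[pr$p2]
  } else {
    w <- base + q
    neg <- w < 0
    n_neg <- sum(neg)
    if (n_neg > 0L) w[neg] <- 0
    ns <- N
    if (sum(w > 0) < 2L) {
      return(list(extinct = TRUE, env = env, n_survivors = ns,
                  mean_viability = mean(w), n_neg = n_neg))
    }
    pr <- sample_pairs(N, N, w)
    p1 <- pr$p1
    p2 <- pr$p2
  }
  list(extinct = FALSE,
       dA = (runif(N) < dA[p1] / 2) + (runif(N) < dA[p2] / 2),
       dB = (runif(N) < dB[p1] / 2) + (runif(N) < dB[p2] / 2),
       env = env, n_survivors = ns, mean_viability = mean(w), n_neg = n_neg)
}

#' Advance a population by one generation
#'
#' Looks up the environment for the generation index, draws one SGE
#' perturbation per individual, applies viability selection (or fecundity
#' weighting in symmetric mode), and mates the survivors back up to
#' constant size `N`. The returned summary describes this generation's
#' pre-selection population and its survivor count.
#'
#' @param pop Population tibble of size `params$N`.
#' @param generation 0-based generation index (drives the environment
#'   schedule).
#' @param params An [model_params()] object.
#' @return A list with elements `population` (the offspring tibble of size
#'   `N`) and `summary` (a one-row tibble: generation, env, allele
#'   frequencies, observed/expected heterozygosity at both loci, survivor
#'   count, mean realized viability).
#' @section Reproduction failure: if fewer than 2 individuals survive
#'   selection the replicate cannot continue; a condition of class
#'   `"sgesim_extinction"` is signalled. Experiment drivers catch it, flag
#'   the replicate extinct and exclude it from frequency averages.
#' @export
step_generation <- function(pop, generation, params) {
  validate_population(pop)
  if (nrow(pop) != params$N) abort("`pop` must have exactly `params$N` rows.")
  st <- step_raw(pop$dosage_A, pop$dosage_B, generation, params)
  if (isTRUE(st$extinct)) {
    abort(sprintf("Population extinct at generation %d (%d survivors).",
                  generation, st$n_survivors),
          class = "sgesim_extinction")
  }
  if (st$n_neg > 0L) {
    warn(sprintf("%d fitness values below 0 truncated in symmetric mode.",
                 st$n_neg))
  }
  list(
    population = new_population(st$dA, st$dB),
    summary = population_summary(pop$dosage_A, pop$dosage_B, generation,
                                 st$env, st$n_survivors, st$mean_viability)
  )
}

#' Simulate one replicate trajectory
#'
#' Runs `params$n_generations` one-generation steps from an initial
#' population, recording the per-generation summary statistics. The RNG
#' state is seeded from `params$seed` unless `seed = NULL`.
#'
#' @param params An [model_params()] object.
#' @param init Initial population tibble; defaults to Hardy-Weinberg
#'   proportions at frequency 0.5 for both loci.
#' @param seed Seed for this trajectory (default `params$seed`); `NULL`
#'   leaves the RNG state untouched.
#' @return A tibble of class `sge_trajectory`, one row per simulated
#'   generation, with attribute `extinct` (TRUE if the replicate died out
#'   before the horizon) and the final population in attribute
#'   `final_population`.
#' @examples
#' p <- model_params(N = 50, S = 0.5, sigma_BB = 0.5, n_generations = 20)
#' traj <- simulate_trajectory(p)
#' traj[1:3, c("generation", "freq_A", "freq_B")]
#' @export
simulate_trajectory <- function(params, init = NULL, seed = params$seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(init)) init <- hwe_population(params$N, 0.5, 0.5)
  validate_population(init, "init")
  if (nrow(init) != params$N) abort("`init` must have exactly `params$N` rows.")
  dA <- init$dosage_A
  dB <- init$dosage_B
  rows <- vector("list", params$n_generations)
  extinct <- FALSE
  n_neg_total <- 0L
  for (g in seq_len(params$n_generations) - 1L) {
    st <- step_raw(dA, dB, g, params)
    rows[[g + 1L]] <- population_summary(dA, dB, g, st$env, st$n_survivors,
                                         st$mean_viability)
    n_neg_total <- n_neg_total + st$n_neg
    if (st$extinct) {
      extinct <- TRUE
      rows <- rows[seq_len(g + 1L)]
      break
    }
    dA <- st$dA
    dB <- st$dB
  }
  if (n_neg_total > 0L) {
    warn(sprintf("%d fitness values below 0 truncated in symmetric mode.",
                 n_neg_total))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sge_trajectory", class(out))
  attr(out, "extinct") <- extinct
  attr(out, "params") <- params
  attr(out, "final_population") <- if (extinct) NULL else new_population(dA, dB)
  out
}
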