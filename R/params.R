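#' Simulation parameters
#'
#' Bundles and validates every constant of the two-locus model: the selected
#' locus A (alleles `A`/`a`) experiences environment-dependent viability
#' selection of strength `S`, while the modifier locus B (alleles `B`/`b`)
#' sets the standard deviation of a Gaussian, non-heritable per-individual
#' fitness perturbation (stochastic gene expression, SGE). Genotype `BB`
#' yields standard deviation `sigma_BB`, `Bb` yields `hb * sigma_BB`, and
#' `bb` yields 0, so `sigma_BB >= sigma_Bb >= sigma_bb = 0` holds for every
#' valid `hb`.
#'
#' @param N Population size (integer, at least 2). Constant across
#'   generations.
#' @param S Selection coefficient at locus A, in `[0, 1]`.
#' @param h1,h2 Degree of dominance at locus A in environments 1 and 2, each
#'   in `[0, 1]`. `h = 0` makes the locally deleterious allele fully
#'   recessive, `h = 1` fully dominant.
#' @param hb Degree of dominance at the modifier locus, in `[0, 1]`.
#' @param sigma_BB Standard deviation of the SGE fitness perturbation for
#'   genotype `BB` (fitness units, non-negative).
#' @param t_switch Environment-switch interval in generations: a positive
#'   integer, or `Inf` for a permanently stable environment 1.
#' @param selection_mode Either `"absorbing_viability"` (survival
#'   probability equal to viability clamped into `[0, 1]`) or
#'   `"symmetric_fecundity"` (no upper fitness boundary; mating probability
#'   proportional to fitness relative to the population maximum).
#' @param n_generations Run length for fixed-horizon experiments.
#' @param n_replicates Number of independent replicate trajectories.
#' @param seed Master RNG seed (integer). Per-replicate streams are derived
#'   from it; see [derive_seed()].
#'
#' @return An object of class `sge_params`: a validated named list.
#' @examples
#' p <- model_params(N = 100, S = 0.5, sigma_BB = 0.1, t_switch = 10)
#' sge_sigma(0:2, p$sigma_BB, p$hb)
#' @export
model_params <- function(N = 1000, S = 0, h1 = 0.5, h2 = 0.5, hb = 0.5,
                         sigma_BB = 0, t_switch = Inf,
                         selection_mode = c("absorbing_viability",
                                            "symmetric_fecundity"),
                         n_generations = 1000L, n_replicates = 200L,
                         seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  check_count(N, "N", min = 2)
  check_unit_interval(S, "S")
  check_unit_interval(h1, "h1")
  check_unit_interval(h2, "h2")
  check_unit_interval(hb, "hb")
  if (!is.numeric(sigma_BB) || length(sigma_BB) != 1L || is.na(sigma_BB) ||
      sigma_BB < 0) {
    abort("`sigma_BB` must be a single non-negative number.")
  }
  if (!is.numeric(t_switch) || length(t_switch) != 1L || is.na(t_switch) ||
      t_switch <= 0 || (is.finite(t_switch) && t_switch != floor(t_switch))) {
    abort("`t_switch` must be a positive integer number of generations or Inf.")
  }
  check_count(n_generations, "n_generations", min = 1)
  check_count(n_replicates, "n_replicates", min = 1)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed)) {
    abort("`seed` must be a single integer.")
  }
  structure(
    list(N = as.integer(N), S = as.numeric(S), h1 = as.numeric(h1),
         h2 = as.numeric(h2), hb = as.numeric(hb),
         sigma_BB = as.numeric(sigma_BB), t_switch = as.numeric(t_switch),
         selection_mode = selection_mode,
         n_generations = as.integer(n_generations),
         n_replicates = as.integer(n_replicates),
         seed = as.numeric(seed)),
    class = "sge_params"
  )
}

#' @export
print.sge_params <- function(x, ...) {
  cat("<sge_params>\n")
  cat(sprintf("  N = %d, S = %g, h1 = %g, h2 = %g, hb = %g\n",
              x$N, x$S, x$h1, x$h2, x$hb))
  cat(sprintf("  sigma_BB = %g (Bb: %g, bb: 0), t_switch = %s\n",
              x$sigma_BB, x$hb * x$sigma_BB, format(x$t_switch)))
  cat(sprintf("  mode = %s, generations = %d, replicates = %d, seed = %d\n",
              x$selection_mode, x$n_generations, x$n_replicates,
              as.integer(x$seed)))
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(x)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(x)
}

#' Derive a reproducible child seed from a master seed
#'
#' Replicate and sweep-cell RNG streams are spawned from the master seed by
#' mixing in the stream index with a fixed multiplicative congruential step,
#' keeping every derived seed a valid 32-bit integer. Identical
#' (master, index) pairs always produce the same stream, so each replicate
#' is individually reproducible.
#'
#' @param seed Master seed (integer).
#' @param index Non-negative stream index.
#' @param stream Multiplier choosing an independent family of streams
#'   (replicates and sweep cells use different families).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index, stream = 48271) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (abs(as.numeric(seed)) %% m + (as.numeric(index) + 1) * stream) %% m
  as.integer(s %% (m - 1)) + 1L
}
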