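#' Population containers
#'
#' A population is a tibble with one row per diploid individual and two
#' integer columns, `dosage_A` and `dosage_B`: the number of copies (0, 1
#' or 2) of the uppercase allele (`A`, `B`) the individual carries at each
#' locus. Dosage is the canonical genotype representation here: the two
#' loci recombine freely and every fitness effect depends only on dosage,
#' so phase never matters.
#'
#' @name sge_population
NULL

new_population <- function(dosage_A, dosage_B) {
  stopifnot(length(dosage_A) == length(dosage_B))
  out <- tibble(dosage_A = as.integer(dosage_A),
                dosage_B = as.integer(dosage_B))
  class(out) <- c("sge_population", class(out))
  out
}

validate_population <- function(pop, arg = "pop") {
  if (!is.data.frame(pop) || !all(c("dosage_A", "dosage_B") %in% names(pop))) {
    abort(sprintf("`%s` must be a population tibble with columns `dosage_A` and `dosage_B`.", arg))
  }
  if (nrow(pop) == 0L) abort(sprintf("`%s` is empty.", arg))
  if (!all(pop$dosage_A %in% 0:2) || !all(pop$dosage_B %in% 0:2)) {
    abort(sprintf("`%s` has dosages outside {0, 1, 2}.", arg))
  }
  invisible(pop)
}

#' Build a population at Hardy-Weinberg equilibrium
#'
#' Each individual's dosage at each locus is drawn independently as the sum
#' of two Bernoulli allele draws at the given allele frequency, i.e. a
#' Binomial(2, freq) sample; the two loci are independent. This is the
#' stochastic realization of Hardy-Weinberg proportions used as the initial
#' condition of the modifier experiments (frequency 0.5 at both loci).
#'
#' @param N Number of individuals (at least 2).
#' @param freq_A,freq_B Allele frequencies of `A` and `B` in `[0, 1]`.
#' @return A population tibble (see [sge_population]).
#' @examples
#' pop <- hwe_population(1000, 0.5, 0.5)
#' allele_frequency(pop, "A")
#' @export
hwe_population <- function(N, freq_A = 0.5, freq_B = 0.5) {
  check_count(N, "N", min = 2)
  check_unit_interval(freq_A, "freq_A")
  check_unit_interval(freq_B, "freq_B")
  new_population(rbinom(N, 2L, freq_A), rbinom(N, 2L, freq_B))
}

#' Build a deterministic population seeded with rare-allele copies
#'
#' Places exactly `n_copies_a` copies of the deleterious allele `a`,
#' one heterozygote per copy while heterozygotes fit (a single new mutant
#' copy at frequency 1/2N can only reside in a heterozygote), homozygotes
#' `aa` only once all `N` individuals carry one copy. Locus B is monomorphic
#' at a caller-chosen genotype (`"BB"` for the fixation experiments, so the
#' SGE magnitude is the constant `sigma_BB`). No random numbers are
#' consumed.
#'
#' @param N Number of individuals.
#' @param n_copies_a Copies of allele `a` to place, in `[0, 2N]`.
#' @param genotype_B One of `"BB"`, `"Bb"`, `"bb"`: the uniform genotype at
#'   the modifier locus.
#' @return A population tibble.
#' @examples
#' seeded_population(1000, 1)            # the 1/2N initial condition
#' @export
seeded_population <- function(N, n_copies_a = 1, genotype_B = "BB") {
  check_count(N, "N", min = 2)
  check_count(n_copies_a, "n_copies_a", min = 0)
  if (n_copies_a > 2 * N) abort("`n_copies_a` cannot exceed 2N.")
  dB <- switch(match.arg(genotype_B, c("BB", "Bb", "bb")),
               BB = 2L, Bb = 1L, bb = 0L)
  n_aa <- max(0L, as.integer(n_copies_a) - N)
  n_het <- as.integer(n_copies_a) - 2L * n_aa
  dA <- rep(c(0L, 1L, 2L), c(n_aa, n_het, N - n_aa - n_het))
  new_population(dA, rep(dB, N))
}

#' Allele frequency at one locus
#'
#' Frequency of the uppercase allele: total dosage divided by `2 * N`.
#'
#' @param pop A population tibble.
#' @param locus `"A"` or `"B"`.
#' @return A proportion in `[0, 1]`.
#' @export
allele_frequency <- function(pop, locus = c("A", "B")) {
  validate_population(pop)
  locus <- match.arg(locus)
  d <- if (locus == "A") pop$dosage_A else pop$dosage_B
  sum(d) / (2 * length(d))
}

#' Observed and expected heterozygosity at one locus
#'
#' Observed heterozygosity is the fraction of dosage-1 individuals;
#' expected heterozygosity is `2 p (1 - p)` with `p` the allele frequency
#' (at most 0.5 for a biallelic locus). The modifier can raise
#' heterozygosity at a selected locus under fluctuating environments even
#' while being disfavoured itself, so both statistics are tracked per
#' generation.
#'
#' @inheritParams allele_frequency
#' @return A one-row tibble with columns `locus`, `observed`, `expected`.
#' @examples
#' heterozygosity(hwe_population(100, 0.5, 0.5), "A")
#' @export
heterozygosity <- function(pop, locus = c("A", "B")) {
  validate_population(pop)
  locus <- match.arg(locus)
  d <- if (locus == "A") pop$dosage_A else pop$dosage_B
  p <- sum(d) / (2 * length(d))
  tibble(locus = locus,
         observed = mean(d == 1L),
         expected = 2 * p * (1 - p))
}

#' Deterministic micro-populations for tests and examples
#'
#' @param name Fixture label: `"all_het"` (every individual heterozygous at
#'   both loci), `"one_mutant"` (one `Aa` heterozygote, the rest `AA`, all
#'   `BB`), or `"hwe_exact_8"` (8 individuals with genotype counts exactly
#'   2/4/2 at each locus).
#' @param N Number of individuals (ignored by `"hwe_exact_8"`, which is
#'   always 8).
#' @return A population tibble.
#' @export
fixture_population <- function(name, N = 4) {
  check_count(N, "N", min = 2)
  known <- c("all_het", "one_mutant", "hwe_exact_8")
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    abort(sprintf("Unknown fixture label; available: %s.",
                  paste0('"', known, '"', collapse = ", ")))
  }
  switch(name,
    all_het = new_population(rep(1L, N), rep(1L, N)),
    one_mutant = seeded_population(N, 1, "BB"),
    hwe_exact_8 = new_population(rep(c(0L, 1L, 2L), c(2, 4, 2)),
                                 rep(c(2L, 1L, 0L), c(2, 4, 2)))
  )
}

## one-row tibble of per-generation statistics; hot path works on raw vectors
population_summary <- function(dA, dB, generation, env, n_survivors,
                               mean_viability) {
  pA <- sum(dA) / (2 * length(dA))
  pB <- sum(dB) / (2 * length(dB))
  tibble(generation = generation, env = env,
         freq_A = pA, freq_B = pB,
         exp_het_A = 2 * pA * (1 - pA), exp_het_B = 2 * pB * (1 - pB),
         obs_het_A = mean(dA == 1L), obs_het_B = mean(dB == 1L),
         n_survivors = n_survivors, mean_viability = mean_viability)
}
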