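#' Genotype-determined base viability
#'
#' The deterministic part of viability, before the SGE perturbation `q` is
#' added. In environment 1 genotypes `AA`, `Aa`, `aa` (dosages 2, 1, 0)
#' have viability `1`, `1 - h1 * S`, `1 - S`; in environment 2 the roles of
#' the alleles reverse: `1 - S`, `1 - h2 * S`, `1`. Allele `A` is therefore
#' adaptive in environment 1 and allele `a` in environment 2.
#'
#' @param dosage_A Integer vector of `A`-allele dosages (0, 1 or 2).
#' @param env Environment label, 1 or 2.
#' @param S Selection coefficient in `[0, 1]`.
#' @param h1,h2 Dominance degrees in environments 1 and 2.
#' @return Numeric vector of base viabilities.
#' @examples
#' base_viability(2:0, env = 1, S = 0.9)   # 1.00 0.55 0.10
#' @export
base_viability <- function(dosage_A, env, S, h1 = 0.5, h2 = 0.5) {
  if (!all(env %in% c(1, 2)) || length(env) != 1L) {
    abort("`env` must be 1 or 2.")
  }
  if (!all(dosage_A %in% 0:2)) abort("`dosage_A` must be in {0, 1, 2}.")
  tab <- if (env == 1) c(1 - S, 1 - h1 * S, 1) else c(1, 1 - h2 * S, 1 - S)
  tab[dosage_A + 1L]
}

#' SGE magnitude set by the modifier genotype
#'
#' Maps the modifier-locus dosage to the standard deviation of the
#' per-individual Gaussian fitness perturbation: `BB` (dosage 2) gives
#' `sigma_BB`, `Bb` gives `hb * sigma_BB`, `bb` gives exactly 0, so the
#' ordering `sigma_BB >= sigma_Bb >= sigma_bb = 0` holds for all valid
#' `hb`.
#'
#' @param dosage_B Integer vector of `B`-allele dosages (0, 1 or 2).
#' @param sigma_BB Standard deviation for genotype `BB` (non-negative).
#' @param hb Dominance degree at the modifier locus.
#' @return Numeric vector of standard deviations.
#' @export
sge_sigma <- function(dosage_B, sigma_BB, hb = 0.5) {
  if (!is.numeric(sigma_BB) || length(sigma_BB) != 1L || sigma_BB < 0) {
    abort("`sigma_BB` must be a single non-negative number.")
  }
  check_unit_interval(hb, "hb")
  if (!all(dosage_B %in% 0:2)) abort("`dosage_B` must be in {0, 1, 2}.")
  c(0, hb, 1)[dosage_B + 1L] * sigma_BB
}

#' Draw SGE fitness perturbations
#'
#' One Normal(0, sigma) draw per individual per generation, at selection
#' time. The perturbation is non-heritable: it is never stored across
#' generations. `sigma = 0` returns exactly 0.
#'
#' @param sigma Standard deviation, a scalar or per-individual vector.
#' @param n Number of draws (defaults to `length(sigma)`).
#' @return Numeric vector of `n` perturbations.
#' @export
draw_sge <- function(sigma, n = length(sigma)) {
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  rnorm(n, mean = 0, sd = sigma)
}

#' Realized viability with boundary treatment
#'
#' Adds the SGE perturbation to the base viability and applies the boundary
#' rule of the selection mode. Under `"absorbing_viability"` values below 0
#' and above 1 are absorbed at 0 and 1 (viability is a survival
#' probability). Under `"symmetric_fecundity"` the upper boundary is
#' removed so fitness can exceed 1 and the perturbation stays symmetric; a
#' mating weight cannot be negative, so values below 0 are still truncated
#' at 0 (with the parameters used for that mode essentially no individual
#' is affected).
#'
#' @param base Numeric vector of base viabilities.
#' @param q Numeric vector of SGE perturbations.
#' @param mode `"absorbing_viability"` or `"symmetric_fecundity"`.
#' @return Numeric vector of realized viabilities / fitnesses.
#' @examples
#' realized_viability(1, 0.3)                            # absorbed at 1
#' realized_viability(1, 0.3, "symmetric_fecundity")     # 1.3
#' @export
realized_viability <- function(base, q,
                               mode = c("absorbing_viability",
                                        "symmetric_fecundity")) {
  mode <- match.arg(mode)
  w <- base + q
  if (mode == "absorbing_viability") pmin(pmax(w, 0), 1) else pmax(w, 0)
}

#' Expected viability after absorbing the Gaussian perturbation
#'
#' Closed-form expectation of `clamp(base + q, 0, 1)` for
#' `q ~ Normal(0, sigma)`, i.e. the exact per-genotype survival probability
#' under absorbing-boundary viability selection. This is what makes the
#' symmetric perturbation asymmetric in its fitness consequences: near the
#' upper boundary the expectation falls below the base viability, near the
#' lower boundary it rises above it. Used by the exact Markov-chain oracle.
#'
#' @param base Base viability (vectorized).
#' @param sigma SGE standard deviation (vectorized).
#' @return Expected clamped viability in `[0, 1]`.
#' @export
expected_clamped_viability <- function(base, sigma) {
  n <- max(length(base), length(sigma))
  base <- rep_len(base, n)
  sigma <- rep_len(sigma, n)
  out <- pmin(pmax(base, 0), 1)
  pos <- sigma > 0
  if (any(pos)) {
    b <- base[pos]; s <- sigma[pos]
    alpha <- (0 - b) / s
    beta <- (1 - b) / s
    # P(X > 1) + E[X; 0 < X < 1] for X ~ N(b, s)
    out[pos] <- (1 - pnorm(beta)) +
      b * (pnorm(beta) - pnorm(alpha)) - s * (dnorm(beta) - dnorm(alpha))
  }
  out
}
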