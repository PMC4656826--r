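---
title: "The SGE modifier model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SGE modifier model: methods and design notes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgesim)
```

## The model

`sgesim` simulates a diploid, monoecious Wright–Fisher population of
constant size $N$ with discrete, non-overlapping generations and two
freely recombining biallelic loci, without mutation.

**Locus A** is the selected locus. In environment 1 the genotypes $AA$,
$Aa$, $aa$ have baseline viability $1$, $1 - h_1 S$, $1 - S$; in
environment 2 the table reverses to $1 - S$, $1 - h_2 S$, $1$. The two
environments alternate deterministically every $T$ generations, starting
in environment 1, so selection of strength $S \in [0, 1]$ always favours
one allele and disfavours the other, with dominance degrees
$h_1, h_2 \in [0, 1]$ controlling the heterozygote.

**Locus B** is the modifier of stochastic gene expression (SGE). Each
generation, at selection time, every individual draws one perturbation
$q \sim \mathcal{N}(0, \sigma)$ added to its baseline viability, where
$\sigma$ is set by the individual's locus-B genotype:
$\sigma_{BB} \ge \sigma_{Bb} = h_b\,\sigma_{BB} \ge \sigma_{bb} = 0$.
The perturbation models non-heritable expression noise: it is drawn
fresh each generation, never stored, and never transmitted. Genotype
$bb$ is exactly noise-free — an idealisation that isolates the
modifier's effect.

**Boundaries.** Viability is a survival probability, so it is truncated
at the absorbing boundaries 0 and 1. This is the load-bearing
assumption: the truncation makes the symmetric Gaussian perturbation
asymmetric in its consequences. An individual whose baseline sits at the
optimum (viability 1) can only be harmed by noise; one near viability 0
can only be helped. `expected_clamped_viability()` gives the closed form
of $\mathbb{E}[\mathrm{clamp}(b + q, 0, 1)]$ (a truncated-normal partial
expectation), which quantifies this: it is below $b$ near the upper
boundary and above $b$ near the lower one.

**Life cycle.** Each generation: (1) look up the environment; (2) draw
$q$ per individual and clamp; (3) each individual survives an
independent Bernoulli trial with probability equal to its realized
viability; (4) survivors mate at random — for each of the $N$ offspring
an ordered pair of two *distinct* parents is drawn uniformly (redrawn
independently per offspring, so a parent can appear in many pairs but
each mating event yields one offspring), and the offspring receives one
uniformly chosen allele from each parent at each locus independently
(free recombination is exactly independent Mendelian transmission).

**Symmetric fecundity mode.** To separate the boundary effect from
everything else, `selection_mode = "symmetric_fecundity"` removes the
upper boundary (fitness may exceed 1) and replaces survival with
fecundity: nobody dies, and mating probability is fitness relative to
the population maximum. In this mode, with $S = 0.5$ and
$\sigma_{BB} = 0.1$, the perturbation is effectively symmetric and the
modifier behaves neutrally — which is the control establishing that the
absorbing boundary, not something else in the life cycle, drives the
modifier's fate in the main mode.

## Parameters

| parameter | meaning | units / range | default |
|---|---|---|---|
| `N` | population size | individuals, ≥ 2 | 1000 |
| `S` | selection coefficient at locus A | dimensionless, [0, 1] | 0 |
| `h1`, `h2` | dominance at locus A per environment | [0, 1] | 0.5 |
| `hb` | dominance at the modifier locus | [0, 1] | 0.5 |
| `sigma_BB` | SGE standard deviation of genotype BB | fitness units, ≥ 0 | 0 |
| `t_switch` | environment-switch interval | generations; `Inf` = stable | `Inf` |
| `selection_mode` | boundary treatment | absorbing / symmetric | absorbing |
| `n_generations` | horizon of modifier runs | generations | 1000 |
| `n_replicates` | replicate trajectories | count | 200 |

The defaults mirror the study conditions: additive effects
($h_1 = h_2 = h_b = 0.5$), $N = 1000$, a 1000-generation horizon, and
Hardy–Weinberg initial frequencies of 0.5 at both loci for modifier
experiments. Fixation experiments instead seed exactly one copy of the
deleterious allele (frequency $1/2N$) with the modifier locus fixed for
$B$, so $\sigma = \sigma_{BB}$ throughout.

## Experiment drivers

* `run_fixation_experiment()` runs each replicate to absorption at
  locus A and reports the fixation probability of the deleterious
  allele, also relative to the neutral expectation (its initial
  frequency). Optional outer meta-replication attaches a standard
  deviation.
* `run_modifier_experiment()` runs a fixed horizon and reports the
  replicate-averaged final frequency of allele $B$; "enhanced SGE is
  advantageous" is the call that this mean exceeds the initial 0.5.
  Starts: Hardy–Weinberg at both loci, locus A fixed for $A$, or fixed
  for $a$.
* `run_sweep()` maps a tibble of parameter combinations to one
  aggregate row per cell, with per-cell derived seeds;
  `dominance_grid()` provides the preset $h_1 \times h_2 \times h_b$
  grid at $N = 1000$.

## The exact oracle

`markov_oracle()` builds the full Markov chain of this same life cycle
on genotype-count states $(n_{AA}, n_{Aa}, n_{aa})$ for $N \le 4$, with
per-genotype survival probabilities obtained from the closed-form
clamped expectation, exact ordered distinct-pair mating probabilities,
and multinomial offspring counts, then solves the linear absorption
system. It yields exact fixation, loss and extinction probabilities per
initial copy number. Because it shares no code path with the simulation
loop (it never draws a random number), it serves as an independent
check: the Monte-Carlo drivers are validated against it on a grid of
$(S, \sigma)$ values in the test suite, and the neutral case reproduces
the martingale $P(\text{fix}) = k/2N$ exactly.

## Numerical and design choices

* **Survival sampling.** The model states viability selection but not
  its sampling mechanism; survival is an independent Bernoulli trial
  with success probability equal to realized viability, the standard
  reading of viability as survival probability.
* **Mating pairs.** A "pair" is two distinct individuals (no selfing);
  monoecy means any two can pair. Pairs are redrawn independently per
  offspring. In fecundity mode the first parent is drawn proportionally
  to weight and the second proportionally among the rest.
* **Extinction.** If fewer than 2 individuals survive (or fewer than 2
  have positive weight), the replicate is terminated and flagged
  extinct; extinct replicates are excluded from frequency averages and
  counted separately. Resampling survivors instead would bias selection
  strength.
* **Environment indexing.** Generations are 0-based; environment blocks
  are $[0, T), [T, 2T), \dots$, so the initial environment is 1 and the
  first switch happens at generation $T$.
* **Early stopping.** Once both loci are monomorphic the
  allele-frequency state cannot change (no mutation), so modifier runs
  skip the remaining generations by default and carry the frequencies
  to the horizon. The only difference from full simulation is the
  skipped tail's residual extinction risk, negligible away from lethal
  parameter corners (it would require essentially the whole population
  to die in one generation); a unit test verifies identical final
  frequencies with early stopping on and off. Disable with
  `early_stop = FALSE` (automatic when recording trajectories).
* **Negative fitness in symmetric mode.** The symmetric mode's
  parameters ($S = 0.5$, $\sigma_{BB} = 0.1$) make negative fitness
  essentially impossible, but a mating weight cannot be negative, so
  residual negative values are truncated at 0 and a warning reports how
  many (observed rate in practice: a handful per $10^8$ draws).
* **Seeding.** Every replicate and every sweep cell gets its own seed
  derived from the master seed by `derive_seed()` (index mixed in by a
  fixed multiplicative step, distinct stream families for replicates
  and cells), so runs are bit-identical given the same seed and any
  single replicate can be reproduced alone.
* **Initial conditions.** Hardy–Weinberg initialization samples each
  individual's dosage as Binomial(2, 0.5) — the stochastic realization
  of HWE proportions — rather than placing deterministic expected
  counts; replicate averaging absorbs the extra variance. Rare-allele
  seeding places one heterozygote per copy: a single new mutant copy
  can only reside in a heterozygote.

## Statistical design of the test suite

Monte-Carlo checks compare estimates against exact references (the
oracle, binomial/multinomial expectations) at 3 standard errors for
single quantities, and chi-square goodness-of-fit at significance
$10^{-3}$ for count tables. Where many cells are checked at once (the
27-cell driver-vs-oracle grid), per-cell z-scores are combined into a
joint chi-square statistic at the same $10^{-3}$ significance with a
gross per-cell guard, since 27 simultaneous 3-SE bands would reject a
correct implementation several percent of the time. Problem sizes used
by the tests and the acceptance script — 3,000 replicates per oracle
cell, 40,000 for the neutral martingale, 20,000 for the
fixation-probability experiment at $N = 1000$, 100–400 replicates of
1,000 generations for the modifier scenarios — were chosen so
Monte-Carlo standard errors are comfortably inside each claim's margin.

## What the simulations do and do not show

The generator *is* the model: closed population of constant size, two
biallelic loci, free recombination, no mutation, deterministic
environmental alternation, Gaussian noise with genotype-determined
standard deviation. Real populations violate most of these —
environments fluctuate stochastically, expression noise is
mechanistically structured (bursting, decay kinetics) and rarely
Gaussian on the fitness scale, modifier and target loci may be linked,
and many loci contribute to a trait. Passing tests therefore certify
the implementation of this idealised model, not predictions about any
particular organism. Within the model, the robust qualitative findings
are: enhanced SGE is always deleterious in stable environments;
under viability selection with absorbing boundaries it becomes
advantageous only under very strong selection with frequent switching
(wider conditions when the selected locus is monomorphic); and removing
the boundary asymmetry (symmetric fecundity mode) makes the modifier
neutral.

## Known limitations

* The exact oracle is limited to $N \le 4$; beyond that the
  genotype-count state space grows too fast for exact transition
  enumeration to stay worthwhile.
* Fixation-time distributions are not reported, only absorption
  outcomes and generation counts per replicate.
* No linkage: the model's free-recombination assumption is hard-coded;
  partial linkage between modifier and target is out of scope.
* The per-replicate seed-spawning scheme is a simple congruential mix —
  adequate for these stream counts, but not a cryptographic guarantee
  of stream independence.
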