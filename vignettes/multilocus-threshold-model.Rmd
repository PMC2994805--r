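---
title: "A multilocus threshold model of MS genetic susceptibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multilocus threshold model of MS genetic susceptibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mssusmod)
library(dplyr)
```

## The model

Multiple sclerosis clusters in families in proportion to genetic sharing:
monozygotic co-twins of a case have a ~25% lifetime risk, first-degree
relatives 2–5%, second-degree 1–2%, third-degree under 1%, against a
population prevalence of 0.1–0.2%. `mssusmod` implements a threshold
("n-of-x") liability model that confronts these observations with the one
firmly established susceptibility locus, HLA DRB1 (carrier frequency
`h = 0.24` in the general population, `h_m = 0.55` among cases):

* there are `x + 1` unlinked, autosomal susceptibility loci — the HLA
  locus plus `x` others;
* each non-HLA locus is in a "susceptible allelic state" with mean
  population frequency `f = h / r`, where the ratio `r` is the free
  parameter that scans state frequencies from near 0 to near 1;
* a non-HLA locus is dominant (state = carrying at least one
  susceptibility allele), recessive (state = homozygous), or mixed (one
  dominant-acting and one recessive-acting allele); the model's
  *composition* is the fraction of loci in each class;
* an individual is genetically susceptible iff at least `n` of the
  `x + 1` loci are in a susceptible state; and
* a susceptible individual develops MS with penetrance `Pt1*` (HLA
  carriers) or `Pt0*` (non-carriers). The default `Pt* = 0.134` is the
  monozygotic concordance rate 0.25 shrunk by the sibling/dizygotic ratio
  2.9/5.4, removing the effect of the shared intrauterine and early
  postnatal environment; dizygotic-twin predictions re-inflate the
  penetrance by that ratio.

Susceptibility is binary by construction: the set-theoretic argument in
the source analysis shows that an arbitrarily complicated collection of
determinative genotype combinations is represented, for the purpose of
prevalence and recurrence computation, by a fixed threshold `n` and the
mean state frequency `f`. The package takes that reduction as its
starting point and does not model the underlying combination structure.

## What pins down the parameters

Because 45% of cases lack the HLA allele, a susceptible individual's `n`
involved loci avoid the HLA locus with probability equal to the
falling-factorial ratio implemented by `hla_negative_fraction()`; setting
it equal to `C* = C/(1 - h) = 0.45/0.76` ties `x` to `(n, r)`.
`solve_x()` finds the continuous root (bisection to 1e-10) and scans
integers `x` in `[max(n, 4), 2000]`, keeping those whose ratio falls
within `C* ± tol` (default `tol = 0.05`, inclusive bounds on the
unrounded `C*`).

```{r}
solve_x(n = 4, r = 2) # the worked example: root 15.9
```

`prevalence()` evaluates the population prevalence by summing, over the
individual's HLA state, the penetrance times the binomial upper tail of
the non-HLA state count. `limit_prevalence()` gives the `r -> Inf` floor
(the binomial count tends to a Poisson under the constraint): 1.27% at
`n = 5`, which is why at least ~10 loci must be required for
susceptibility before the predicted prevalence can approach 0.1–0.2%.

Recurrence risks condition on the proband: the parents jointly carry
susceptible states at `n` loci (`n - 1` non-HLA loci for an HLA-positive
proband), split over the dominance classes proportionally to the
composition with largest-remainder rounding — the source never states
this rule, so the package fixes it deterministically. Those conditioned
loci transmit with the closed-form probabilities of
`transmission_probs()` (e.g. the sibling HLA form
`0.5 (1 + 2a - a^2) = 62.0%` at `a = 0.128`), the rest carry the baseline
frequency, and `recurrence_risk()` takes the complement of the convolved
probability that the relative's total count falls short of `n`.
`expected_recurrence()` averages the HLA-positive and HLA-negative
proband branches with weights `1 - C` and `C = 0.45`.

```{r}
p80 <- ms_model(n = 13, r = 4, composition = c(dominant = 0.2, recessive = 0.8))
predict_rates(p80, x = c(100, 107)) |> mutate(rate = round(100 * rate, 2))
```

## Design choices made where the source was open

* **Bracket placement in the recurrence sums.** The printed nested sums
  apply "1 minus" ambiguously; the package computes the complement of
  P(total susceptible-locus count < n), which reduces exactly to the
  prevalence formula when all conditioning probabilities are set to the
  baseline, and respects the printed truncation clauses.
* **Conjugal offspring.** The printed per-locus forms mix a
  both-parents-susceptible branch (weight `(n/x)^2`) into the one-parent
  forms, but the number of loci they apply to is not stated. Applying
  them to the usual `n - 1`/`n` conditioned set predicts ~2–3%, which is
  close to what exact forward simulation of the model gives (~3%), yet
  the published predictions are ~10–12%. Conditioning on *both parents'*
  necessary sets — `2(n-1)` (at least one parent an HLA carrier) or `2n`
  loci, capped at `x` — reproduces all four published conjugal cells to
  within ~0.5 percentage points, so the package adopts that rule. The
  gap between the closed form and the simulator is the acknowledged
  price of the paper-faithful approximation, and `simulate_pedigrees()`
  quantifies it. The two affected parents are both probands, so the
  HLA-negative branch weight is `C^2`.
* **Conjugal HLA form.** The printed conjugal carrier probability
  `0.5 (1 + 2a + a^2)` has a `+` where every analogous formula has `-`;
  the printed form is the default and
  `ms_model(conjugal_ph_corrected = TRUE)` flips the sign.
* **Sibling HLA sharing.** The printed `P_H` assumes a single
  transmitting parent; `p_hla_shared_exact()` enumerates parental
  diplotypes and shows the printed form overestimates by ~2% relative at
  `a = 0.128`. The printed form is always used in predictions; the exact
  form is a diagnostic.
* **`C*` is carried unrounded** (`0.45/0.76 = 0.5921`), with rounding
  conventions available in `solve_x()` for table forensics; the worked
  root 15.9 requires the unrounded value.
* **Integer-range convention.** The literal `C* ± 0.05` scan reproduces
  the published per-cell `x` ranges only approximately (e.g. it admits
  `{10, 11, 12}` where "11–12" was published at `n = 5`, `r = 1`; the
  published band effectively narrows as `n` grows, and the original
  program's exact convention is not recoverable). The published ranges
  for all 112 grid cells ship as a plain-text table
  (`published_x_ranges()`) so predictions can be evaluated at the
  published locus counts; the literal scan remains the default.

## The grid search

`sweep_grid()` scans `r` over {0.25, 0.33, 0.5, 1, 2, 4, 8, 16} and `n`
over 5–60, solves each cell's `x` range, evaluates predictions at the
range endpoints, and scores the cell with the Closeness-of-Fit
```
CoF = sum over targets of [(H - E)/E + (L - E)/E]^2
```
against six observed targets (prevalence 1.5 per-mille; sibling 3.0%,
conjugal offspring ~10%, parent/child 2.0%, second degree 1.0%, third
degree 0.9%). The companion text says five squared deviations are
summed, but recomputing the published per-column CoF values from their
printed high/low entries matches only when all six targets enter
(1.75 -> printed 1.7), so six is the default; drop rows from
`fit_targets()` to probe alternatives. `CoF < 4` (the 1-df chi-square
critical value) marks an acceptable fit. With predictions evaluated at
the published locus counts the optimum lands at 80% recessive loci,
`r = 4`, `n = 13`, `x = 100–107`; all-dominant and all-mixed
architectures never reach CoF < 4, and cells with `r <= 0.5` are
catastrophically poor fits — the same conclusions the source reports.

## The simulator: what it emulates and what it does not

`simulate_cohort()` and `simulate_pedigrees()` realise the model's own
assumptions generatively: founder genotypes in Hardy-Weinberg
proportions at `x + 1` unlinked autosomal loci (mixed loci carry a
three-allele system: dominant-acting, recessive-acting, null), Mendelian
transmission, threshold susceptibility, Bernoulli affection. Rejection
sampling conditions on an affected proband (both parents, for conjugal
families), with a cap and a warning if acceptance falls below 1e-4. A
fixed seed gives byte-identical output; the generator draws all families
in one vectorised stream.

The simulator is the package's oracle: tests verify Hardy-Weinberg
proportions at founders, realised identity-by-descent sharing (0.5 /
0.25 / 0.125 by degree), cohort prevalence against the closed form
within Monte Carlo error, the exactness of the printed `P_h1` and the
documented bias of `P_H`, and the sibling recurrence closed form within
its approximation gap. It emulates the model, not reality: no linkage or
linkage disequilibrium between loci, no environmental structure, no
sex-specific frequencies, no penetrance heterogeneity beyond the
HLA/non-HLA split. Passing oracle tests therefore shows internal
consistency of formulas and code, not epidemiological validity.

## Numerical choices and problem sizes

Binomial, Poisson and convolution arithmetic go through `stats`
(`dbinom`, `pbinom`, `ppois`); the falling-factorial ratio is computed
on the log-gamma scale; root finding uses `uniroot` to 1e-10.
Summation bounds exceeding the available locus counts truncate to zero
terms, as the printed equations prescribe. Tie-breaks in
`find_optimum()` prefer smaller `n`, then smaller `r`. The test suite
enumerates all `2^(x+1)` locus states up to `x = 12` as an exact
prevalence oracle (agreement to 1e-12) and uses cohorts of 2e5 and
pedigree sets of up to 2e5 families for the stochastic oracles; the full
published-grid sweep (112 cells) takes well under a minute.

## Known limitations

* The published per-cell integer `x` ranges cannot be reproduced exactly
  by any stated tolerance convention; the package documents the literal
  scan's differences and ships the published ranges as data.
* The published proband-wise twin concordance rates (31% / 29%) are not
  derivable from the printed pair counts by the standard formula; they
  are treated as data in `twin_table()`.
* The penetrance-bound derivation reproduces the printed ratio limit 1.8
  but gives 0.314 / 0.171 where 0.32 / 0.18 were printed; the exact
  rounding path sits in supplementary material that is not part of this
  implementation.
* Closed-form recurrence predictions are approximations by construction
  (single-transmitting-parent HLA sharing; conjugal conditioning); the
  simulator measures their bias but the package never silently
  substitutes the exact values.
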