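---
title: "An eco-evolutionary model of batch-spawning cod under size-selective fishing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An eco-evolutionary model of batch-spawning cod under size-selective fishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question the model addresses

Multiple-batch spawning — shedding a season's eggs across many separate
batches — is a risk-spreading (bet-hedging) strategy: when whole egg
batches can be wiped out by environmental events, splitting the eggs
reduces the variance of a female's seasonal reproductive success at a
small cost to its mean. The benefit grows with female size, because
larger females shed more batches. Size-selective fishing removes exactly
those large females. `batchspawner` implements an individual-based
eco-evolutionary simulation of an Atlantic cod-like population to ask
how this strategy performs when a fishery selects against the trait the
strategy depends on, and what that means for evolutionary and ecological
recovery after a fishing moratorium.

## The model

Every fish is followed individually through annual time steps. The
evolving trait is the asymptotic length $L_\infty$ of the von
Bertalanffy growth curve.

**Genetics.** The trait is encoded by 10 diploid loci with 0/1 alleles,
so the genotypic score $g = \sum \text{alleles}$ ranges over $0\dots20$.
Offspring inherit one allele per locus from each parent by Mendelian
segregation; there is no mutation, so genetic variance is standing
variation only. At birth the phenotype is fixed for life as
$L_\infty = a + b\,(g + e)$, with $e \sim N(0, 3.5^2)$ on the score
scale. With $a = 60$ cm and $b = 2$ cm/score the mid-range score maps to
80 cm and the narrow-sense heritability of $L_\infty$ is
$b^2 V_g / (b^2(V_g + \sigma_e^2)) \approx 5/17.25 \approx 0.29$, inside
the 0.2–0.3 band reported for cod size traits (heritability is invariant
to the affine map, so $a$ and $b$ only set the scale).

**Growth.** Growth rate is coupled negatively to the trait,
$k = \exp(\alpha + \beta \ln L_\infty)$ with $\beta = -1$, so
large-bodied genotypes grow slowly. Lengths follow annual von
Bertalanffy increments damped by population density:
$$L_{t+1} = L_t + (L_\infty - L_t)\,(1 - e^{-k})\,\max(0,\,1 - \theta B/K),$$
where $B$ is total population biomass (all ages) at the start of the
year and $K$ a fixed biomass scale. The linear multiplier is the
simplest form consistent with "density negatively affects somatic
growth"; $\theta$ defaults to 1 and is configurable.

**Maturation and mortality.** A fish matures (irreversibly) when its
length reaches 66% of its individual $L_\infty$. Weight is allometric,
$W = 3.52\times10^{-6} L^{3.19}$ kg. Natural mortality is applied from
age 3 on at the instantaneous rate $M = 0.15\,\mathrm{yr}^{-1}$,
rising to $0.25$ at maturity through reproductive costs; ages 0–2 are
exempt because pre-recruit mortality is folded into the egg-to-recruit
bottleneck. No fish outlives 25 years.

**Reproduction.** Each mature fish spawns once a year as a dam, with
fecundity $N_{\mathrm{eggs}} = (0.48 (W + 0.37)^{1.45} + 0.12) \times
10^6$ (the leading factor is read as millions of eggs; the literal
alternative of $10^{-6}$ eggs per female cannot sustain any
population). A multiple-batch spawner (MBS) splits the eggs as evenly
as possible over $N_{\mathrm{batches}} = 21.1561 / (1 +
e^{(55.014 - L)/10.141})$ batches (rounded half-up, floored at 1, so
the count saturates at 21 for the largest females); a single-batch
spawner (SBS) sheds one batch. Every batch wholly survives or dies in
an independent Bernoulli trial with survival $(1 - E)(1 - 0.00523\,
(b - 1))$ for the $b$-th MBS batch — environmental forcing $E$ times a
batch-order quality cost rising from 0 to about 0.105 — and $(1 - E)$
for SBS. Surviving eggs pass the egg-to-recruit bottleneck
($1.13\times10^{-6}$, binomial) once, at spawning. Each female's season
uses one sire drawn uniformly from the other mature fish (the model is
unsexed: every mature individual both spawns as a dam and is available
as a sire; selfing occurs only in a pool of one). Recruits enter at age
0 and length 0, and both parents are credited one lifetime recruit per
offspring.

**Fishing.** During the fishing phase every fish strictly longer than
45 cm is captured with probability $F \cdot
\mathrm{logit}^{-1}(-12.5 + 0.25 L)$ (trawl-like selectivity, 0.5 at
50 cm). Fishing stops permanently — a latched moratorium — as soon as
end-of-year biomass falls to 15% of its level in the year fishing
began.

**Annual cycle.** The event order within a year is fixed, because
results are order-sensitive: (1) density ratio from start-of-year
biomass, (2) growth, (3) maturation, (4) spawning and recruitment,
(5) natural mortality, (6) harvest, (7) ageing and the age-25 cull,
with recruits joining at age 0 after ageing, then (8) the annual
record. Records carry abundance, biomass, catch, trait and age
summaries, the full 0–25 age histogram, and per-season spawning
tallies, so every published metric is a pure function of the saved
records and cohort ledger.

**Study design.** A scenario crosses a strategy (MBS/SBS) with a
forcing rate $E \in \{0.05,\dots,0.30\}$ and a fishing rate $F \in
\{0.1, 0.2, 0.3\}$ — 36 scenarios, 50 replicates each in the full
design. Each replicate burns in for 5000 years under forcing only,
then runs a 500-year experiment: 100 pre-fishing years, fishing for at
most 300 years or until the moratorium latches, then forcing only to
year 500. Replicate seeds derive from a master seed by a stable 31-bit
hash of the scenario coordinates, so any cell reproduces bit-identically
in isolation.

## Fitness bookkeeping

Across-generational fitness over a window of birth years is the
geometric mean, over finalized cohorts (all members dead), of each
cohort's mean lifetime recruit output per member. Because every recruit
credits both parents, a demographically stationary population sits near
a cohort mean of 2; a single zero-output cohort drives the geometric
mean of its window to zero, which is exactly the sensitivity to
reproductive failure the statistic is meant to expose (no epsilon
padding is applied). "Generation" is a birth-year cohort; the pre /
during / post windows are the forcing-only years before fishing onset,
the fishing-active years, and the years after the latch. A failed
spawning season is a female-season yielding zero recruits; the
all-batches-died variant can be recovered from the per-batch survival
model. Realized individual fitness is the year's recruit count divided
by the mature-adult count.

## Calibrated constants the source data do not pin down

Three constants of this model family are calibrations rather than
measurements, and two deserve explanation.

**The growth-rate coupling** ($\alpha$ in $k = e^{\alpha}
L_\infty^{\beta}$). The underlying growth data come from an
unexploited, slow-growing high-latitude lake population, but the fitted
coefficients are not available. The choice of $\alpha$ controls the
stock's surplus production, and with it the entire dynamical regime of
the experiment. Fast growth (e.g. $k(80\,\mathrm{cm}) = 0.12$, typical
of southern wild cod stocks) yields early maturation and so much
compensatory headroom that trawling at $F \le 0.3$ never depletes the
stock to the 15% threshold — the moratorium, the fitness collapse and
the recovery phase never happen, and the scenario pipeline degenerates.
The shipped default, $\alpha = \ln 6.6$ so that $k(80\,\mathrm{cm}) =
0.0825\,\mathrm{yr}^{-1}$, was fixed on two structural criteria only,
before any headline quantity was computed: unfished populations must
persist across the whole forcing grid, and the moratorium must be
reachable within the tested fishing rates. This places the stock in a
regime of modest surplus production — slow growth, maturation around
age 12–13 — which is also the regime in which a moratorium is a
meaningful management event. The regime is genuinely knife-edged: the
environmental forcing grid (a factor $0.70/0.95 \approx 0.74$ on
expected recruitment between its ends) and the lightest fishing rate
(a factor of similar size on lifetime reproductive output) compress the
viable band of surplus production from both sides, and high-forcing
replicates occasionally collapse, as expected near the boundary the
source study itself reports (forcing above 0.30 caused frequent
collapses there).

**The biomass scale $K$.** A carrying-capacity calibration rule of the
form "set $K$ to the unfished equilibrium biomass of a pilot run" has
no fixed point here: with the linear density multiplier, equilibrium
biomass is always the fraction $(1 - d^{*})/\theta$ of whatever $K$ is
supplied, where the equilibrium damping $d^{*}$ is set by demography
alone. $K$ is therefore a plain configurable constant, default
6000 kg, chosen so that unfished equilibrium abundance is of the same
order as the 2000-fish founder population. Up to Monte-Carlo noise the
dynamics are invariant to this scale.

**Founder state.** Founders get independent Bernoulli(0.5) alleles,
ages uniform on 1–10, and lengths on their own unsuppressed growth
curve at that age; maturity is evaluated at initialisation.

## Numerical and tie-break conventions

* Batch counts round half-up (`floor(x + 0.5)`), floored at one batch.
* The 45 cm fishing threshold is exclusive (a fish of exactly 45 cm is
  exempt); the maturation threshold (66% of $L_\infty$) and the 15%
  moratorium trigger are inclusive.
* The moratorium compares end-of-year biomass with the biomass recorded
  at the end of the last pre-fishing year and latches permanently.
* Catch biomass uses post-growth weights of the year of capture;
  the density ratio uses start-of-year biomass including all ages.
* Expressed phenotypes are truncated below at 1 cm; genotypic scores
  are never truncated.
* Cohorts with living members are excluded from fitness windows rather
  than padded; pooled percentage comparisons average per-scenario
  ratios of period means.
* An extinct replicate terminates with a flagged record and is carried
  as missing data in summaries.

## What the generator does and does not emulate

The simulator is the study's data source: all inputs are configuration.
It emulates overlapping generations, heritable trait variation with
environmental noise, density-dependent growth, whole-batch
environmental mortality, and size-selective removal with a latched
moratorium. It does not emulate sexes or mate choice (matings are
unsexed and uniform), skipped spawning, indeterminate fecundity,
within-year time steps, space or migration, temperature effects, or
mutation. Passing tests therefore demonstrate the internal consistency
of this mechanism at the stated constants — not that real cod stocks
behave quantitatively like any particular simulated cell.

Two systematic departures from the source study's reported summary
levels are worth knowing about when reading the acceptance output.
First, snapshot mean ages here are computed from full 0–25 pyramids in
which the (mortality-exempt) age 0–2 classes are large, which pulls
abundance-weighted mean ages well below the source's reported ~13
years; the late-maturation regime is visible instead in the maturation
ages. Second, after the moratorium the simulated stock rebuilds through
a density-release boom, so post-fishing cohort fitness can approach or
exceed pre-fishing fitness in low-forcing cells even though pooled
recovery stays incomplete; the source reports a much deeper, more
persistent fitness deficit. Both behaviours are emergent consequences
of the documented design decisions (pyramid definition, finalized-
cohort fitness, mating design), not tuning targets.

## Problem sizes used by the shipped checks

The full design (5000-year burn-ins, 50 replicates, 36 scenarios) is
hours of CPU. The package's own checks run the same pipeline at reduced
scale: the test suite uses scaled-down populations (hundreds of fish)
for engine contracts and a 36-scenario factorial with 500-year burn-ins
and 2 replicates for directional and headline checks;
`scripts/acceptance.R` defaults to 1000-year burn-ins with 5 replicates
per scenario (about ten minutes on one core) and exposes
`--replicates`/`--burn-in` for larger runs. These sizes are the
package's choices for routine verification; headline quantities remain
Monte-Carlo noisy at this scale, which is why the acceptance script
reports the replicate count alongside every value.

## Known limitations

* The demographic regime (hence most scenario-level aggregates) is
  sensitive to the growth-coupling calibration discussed above;
  quantities like median fishing-period lengths should be read as
  regime-dependent.
* Uniform sire choice removes size-selection on the male path, halving
  the selection differential on $L_\infty$ relative to a
  fecundity-weighted mating design.
* The linear density multiplier is one of several defensible forms;
  saturating forms would change compensation strength under depletion.
* Only the evolving trait couples genetics to life history; maturation
  age and size respond to selection solely through $L_\infty$.

```{r example}
library(batchspawner)
cfg <- scenario_config(strategy = "MBS", env_forcing = 0.2,
                       fishing_F = 0.2, burn_in_years = 800, seed = 1)
run <- run_scenario(cfg)
summarize_run(run)
```
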