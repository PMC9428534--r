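# batchspawner

An individual-based eco-evolutionary simulation of an Atlantic cod-like
population, built to ask whether multiple-batch spawning — a
risk-spreading reproductive strategy in which a female sheds her season's
eggs across many separate batches — remains advantageous when the
population is exposed to size-selective fishing, and what that implies
for recovery after a fishing moratorium.

The package is aimed at fisheries and evolutionary ecologists who want a
fully reproducible scenario pipeline: a mechanistic annual-cycle engine,
a factorial experiment runner with per-cell reproducible seed streams,
and the summary statistics used to compare spawning strategies
(geometric-mean across-generational fitness, realized individual
fitness, failed-spawning proportions, fishing-period lengths, age
pyramids).

## The model in brief

Each fish carries a heritable quantitative trait, the von Bertalanffy
asymptotic length *L*∞, encoded by 10 diploid 0/1 loci and expressed
with environmental noise (heritability ≈ 0.29). Growth follows annual
von Bertalanffy increments, density-damped by the biomass ratio *B/K*;
the growth rate is coupled negatively to the trait,
*k* = exp(α − ln *L*∞). Fish mature at 66% of their individual *L*∞,
weigh *W* = 3.52·10⁻⁶ *L*^3.19 kg, and from age 3 die at instantaneous
rate 0.15 yr⁻¹ (0.25 when mature; maximum age 25).

Every mature fish spawns annually with fecundity
(0.48 (*W* + 0.37)^1.45 + 0.12)·10⁶ eggs. A multiple-batch spawner
(MBS) splits them over up to 21 batches (logistic in fork length); a
single-batch spawner (SBS) sheds one batch. Whole batches survive or
die in independent Bernoulli trials with survival
(1 − *E*)(1 − 0.00523 (*b* − 1)), where *E* is the environmental
forcing rate and the second factor the batch-order cost paid only by
MBS. Surviving eggs are thinned once by the egg-to-recruit probability
1.13·10⁻⁶. During the fishing phase, fish longer than 45 cm are
captured with probability *F*·logit⁻¹(−12.5 + 0.25 *L*); fishing stops
permanently once biomass falls to 15% of its pre-fishing level.

A scenario crosses strategy × *E* ∈ {0.05…0.30} × *F* ∈ {0.1, 0.2,
0.3}; the full design is 36 scenarios × 50 replicates with 5000-year
burn-ins. See `vignettes/batch-spawning-model.Rmd` for the complete
model description, calibration rationale and caveats.

## Worked example

One MBS replicate at *E* = 0.2, *F* = 0.2, with a shortened 800-year
burn-in:

```r
library(batchspawner)
cfg <- scenario_config(strategy = "MBS", env_forcing = 0.2,
                       fishing_F = 0.2, burn_in_years = 800, seed = 1)
run <- run_scenario(cfg)
run
#> <scenario_run> MBS E=0.20 F=0.20 seed=1: 516 recorded years, fishing lasted 63 yr
summarize_run(run)[, c("fishing_years", "mean_linf_pre",
                       "mean_linf_during", "fitness_pre",
                       "fitness_during", "fitness_post")]
#>   fishing_years mean_linf_pre mean_linf_during fitness_pre fitness_during fitness_post
#>              63         71.13            69.31        1.80           1.38         2.02
```

Reading the numbers: trawling drove biomass to the 15% moratorium
threshold in 63 years. The mean asymptotic length fell from 71.1 cm
before fishing to 69.3 cm during it — fisheries-induced selection
toward smaller-bodied genotypes. Across-generational fitness (the
geometric mean over birth cohorts of mean lifetime recruit output per
member; ≈ 2 at demographic stationarity because each recruit credits
both parents) dropped from 1.80 to 1.38 while cohorts were being
harvested before reproducing, then rebounded in the density-released
recovery after the moratorium.

A factorial experiment and its strategy comparison:

```r
design <- make_design(master_seed = 1, replicates = 5)   # 36 x 5 cells
exp_out <- run_experiment(design, burn_in_years = 1000)
summ <- summarize_experiment(exp_out)
headline_metrics(summ)      # study-level aggregates
write_outputs(exp_out, "out/")  # CSVs + manifest with checksums
```

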