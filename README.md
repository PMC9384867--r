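# enmpair

Climate-suitability modelling and niche overlap for parasite–host
species pairs.

## The problem

Holoparasitic plants survive only where both the climate suits them
*and* their host grows.  Assessing how climate change reshapes their
range therefore needs three linked analyses per parasite–host pair:

1. **Species distribution models** (presence–background maximum
   entropy) for the parasite and the host, fitted from occurrence
   records and bioclimatic raster layers, tuned over regularization
   multipliers and feature classes by AICc, and evaluated with AUC and
   the true skill statistic (TSS);
2. **Habitat dynamics** under future scenario ensembles: the habitat
   suitability index (HSI ∈ [0,1]) is reclassified into four bins
   (not/low/moderate/high at 0.25/0.50/0.75), area percentages are
   tracked per scenario, and each species is labelled *growing*,
   *declining* or *fluctuating*;
3. **Niche overlap** between parasite and host suitability surfaces,
   measured by Schoener's statistic over normalized per-cell
   suitabilities p<sub>X</sub>, p<sub>Y</sub>:

   D(p_X, p_Y) = 1 − ½ Σᵢ |p_X,i − p_Y,i|,  D ∈ [0, 1]

   with per-pair means compared across pairs by one-way ANOVA and the
   Tamhane T2 post-hoc (compact letter display).

The package implements all three stages as composable functions plus a
one-call pipeline, and ships a synthetic-world generator (Gaussian
random-field climate layers, species with known suitability truth,
presence sampling, scenario perturbations) so the entire analysis runs
and is tested without any external data.

## The model

The maximum-entropy SDM maximizes, over coefficients β on features
f(x) (linear, quadratic, product, hinge and threshold transforms of
the climate variables, scaled to [0,1]),

    (1/m) Σ_presences η(x) − log Σ_background e^{η(x)} − Σ_j λ_j |β_j|,

with η(x) = Σ_j β_j f_j(x) and per-feature penalties
λ_j = RM · r_class(m) · s_j/√m (s_j the feature's presence standard
deviation, r_class the published class-level defaults).  The raw
output q(x) = e^{η(x)}/Z is a probability distribution over the
background; the mapped HSI is the logistic transform
L(x) = c·q/(1 + c·q) with c = e^H (H the entropy of q), so a null
model scores exactly 0.5.  The solver is a working-set proximal-Newton
method (compiled via Rcpp) that matches brute-force optima to ~1e−6.

## Worked example

```r
library(enmpair)

world <- simulate_world(nrows = 60, ncols = 60, K = 6, n_presence = 150,
                        offset_delta = 0.6, seed = 42)
cfg <- default_config(seed = 42, n_background = 2000, n_replicates = 5)
study <- run_study(world$occs, world$pairs, world$scenarios,
                   mask = world$mask, config = cfg)

study$species$parasite$contributions
#>   variable contribution key_factor
#> 1     Bio1       69.100       TRUE
#> 2     Bio4       28.008       TRUE
#> 3     Bio6        2.774      FALSE
#> 4     Bio3        0.118      FALSE
#> 5     Bio2        0.000      FALSE
#> 6     Bio5        0.000      FALSE

study$species$parasite$area_table
#>       scenario pct_not pct_low pct_moderate pct_high pct_suitable
#> 1      current    82.2    6.14         11.7        0         11.7
#> 2 RCP2.6-2050s    80.2    6.53         13.3        0         13.3
#> 3 RCP8.5-2050s    79.1    7.08         13.8        0         13.8
#> 4 RCP2.6-2070s    80.5    6.36         13.2        0         13.2
#> 5 RCP8.5-2070s    77.9    8.25         13.8        0         13.8

study$species$parasite$typology
#> <growing: deltas +1.58, +2.11, +1.47, +2.11>

study$pairs[[1]]
#> <enm_pair_run parasite vs host: D mean 0.4638 +/- 0.0564 (declining)>

round(study$pairs[[1]]$d, 4)
#>      current RCP2.6-2050s RCP8.5-2050s RCP2.6-2070s RCP8.5-2070s
#>       0.5448       0.4809       0.4286       0.4685       0.3961
```

Reading the output: Bio1 and Bio4 are the parasite's *key climate
factors* (percentage contribution > 10%); its suitable habitat
(moderate + high classes) grows from 11.7% of the region to 13.2–13.8%
in every future scenario, hence the *growing* label; the parasite–host
niche overlap is *moderate* (0.40–0.60) and every future value lies
below the current 0.5448, hence the overlap typology *declining* —
the niche offset built into the simulated pair (0.6 standardized
units) widens as the climate shifts.

A command-line interface wraps the same machinery:

```sh
Rscript -e 'enmpair::enm_cli()' simulate --out world --seed 1
Rscript -e 'enmpair::enm_cli()' run-study --world world --out results --seed 1
Rscript -e 'enmpair::enm_cli()' overlap --x a.asc --y b.asc
```

## Layout

| path | contents |
|---|---|
| `R/grid.R` | ESRI ASCII grid I/O, raster stacks, masks, ensembles |
| `R/occurrences.R` | occurrence cleaning, rarefaction, background draws |
| `R/variable-selection.R` | Pearson \|r\| ≤ 0.7 filtering with pilot contributions |
| `R/features.R`, `R/maxent-fit.R`, `src/solver.cpp` | the maximum-entropy engine |
| `R/tuning.R` | AICc tuning, splits, AUC/TSS, replicate ensembles |
| `R/habitat.R` | HSI classification, area summaries, trend typology |
| `R/overlap.R` | Schoener's D, ANOVA, Tamhane T2, letter display |
| `R/synthetic.R` | the synthetic world generator |
| `R/pipeline.R`, `R/cli.R` | study orchestration and CLI |
| `vignettes/enmpair-methods.Rmd` | the methods vignette |
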