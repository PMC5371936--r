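# cohortdem

Stage-structured demographic analysis of daily insect cohort censuses, built
for laboratory life-table experiments on the coffee berry borer
(*Hypothenemus hampei*) — the kind of study that rears cohorts of eggs on
artificial diets (e.g. with and without antibiotics), censuses every
individual daily, follows adult females' oviposition, and asks how a
treatment changes population growth and which life-cycle transition is
responsible.

The package covers the whole chain:

1. **Data model** — validated tabular formats for daily censuses
   (`cohort_id, individual_id, day, stage, status`) and oviposition records
   (`female_id, treatment, day, eggs`), plus JSON round-tripping of
   projection matrices.
2. **Matrix estimation** — pooled interval-aligned transition counting
   turns daily observations into the Lefkovitch matrix

   ```
         | P1  .   .   .   .   F  |
         | G1  P2  .   .   .   .  |
     A = | .   G2  P3  .   .   .  |      N[t+1] = A N[t]
         | .   .   G3  P4  .   .  |
         | .   .   .   G4  P5  .  |
         | .   .   .   .   G5  P6 |
   ```

   with stasis probabilities `P_i`, growth probabilities `G_i` (per 6-day
   interval) and adult fertility `F` estimated as interval-scaled eggs per
   female-day (non-ovipositing females included).
3. **Eigen-demography** — λ (dominant eigenvalue), net reproductive rate
   `R0` via the fundamental matrix, generation time `T = ln R0 / ln λ`,
   stable stage distribution, reproductive values, sensitivities and
   elasticities, and mean ± SE summaries over replicate cohorts.
4. **LTRE** — fixed-design life table response experiment decomposing
   `λ(treatment) − λ(reference)` into per-transition contributions
   `C_ij = Δa_ij · S_ij(midpoint matrix)`, with `G/P/F` class totals and a
   ready-made contribution bar chart.
5. **Treatment statistics** — Pearson chi-square for proportions of
   ovipositing females, per-vial sex-ratio summaries (mean of ratios),
   developmental-time summaries, one-way ANOVA and pairwise Welch/Holm
   post-hocs, exact Poisson oviposition-rate intervals.
6. **Synthetic cohorts** — an individual-based stochastic simulator with
   known ground truth (per-individual gamma stage durations, daily
   mortality hazards, zero-inflated Poisson oviposition), calibrated
   presets for control / penicillin / tetracycline diets, used to validate
   every estimator.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` for each result type.

## Worked example

```r
library(cohortdem)

# simulate a control-like experiment: 5 cohorts x 20 eggs censused daily
# for 50 days, 50 females' oviposition for 60 days
sim <- simulate_cohorts(control_config(seed = 42))
A <- estimate_projection_matrix(sim$census, sim$oviposition, cbb_schema())
A
#> <projection_matrix> 6 stages, interval 6 days
#>             egg  larva prepupa   pupa juvenile adult
#> egg      0.2908 0.0000       0 0.0000   0.0000 1.398
#> larva    0.6454 0.5687       0 0.0000   0.0000 0.000
#> prepupa  0.0000 0.3270       0 0.0000   0.0000 0.000
#> pupa     0.0000 0.0000       1 0.0448   0.0000 0.000
#> juvenile 0.0000 0.0000       0 0.9403   0.0000 0.000
#> adult    0.0000 0.0000       0 0.0000   0.9778 0.990

glance(demography(A))
#> # A tibble: 1 × 4
#>   lambda    R0 T_intervals T_days
#>    <dbl> <dbl>       <dbl>  <dbl>
#> 1   1.23  92.8        21.7   130.
```

The population grows 23% per 6-day interval; a newborn female leaves ~93
offspring over her lifetime; a generation takes ~130 days. Comparing
treatments end to end:

```r
res <- run_pipeline(
  list(control = control_config(), tetracycline = tetracycline_config()),
  reference = "control", seed = 42
)
res$summary
#>   treatment    parameter   mean      se     n
#> 1 control      lambda      1.23 0.00330     5
#> 2 control      R0         94.3  3.82        5
#> 3 control      T_days    133.   0.836       5
#> 4 tetracycline lambda      1.04 0.00273     5
#> 5 tetracycline R0          5.84 0.465       5
#> 6 tetracycline T_days    305.   9.32        5

class_summaries(res$ltre$tetracycline)
#>    term  class contribution
#>  1 G1    G        -0.00273
#>  ...
#> 12 F     F        -0.156
```

Tetracycline-like fertility collapses λ from 1.23 to 1.04 per interval,
and the LTRE attributes almost the entire reduction to the adult fertility
entry `F` (−0.156 of a total ≈ −0.16), not to survival or development —
the demographic signature of a symbiont-mediated fecundity effect.
`autoplot(res$ltre$tetracycline)` draws the corresponding contribution bar
chart.

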