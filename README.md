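# gutcod

Quantitative bioenergetics of controlled-feeding crossover studies, in a
single electron-equivalent currency.

How many of the calories a person eats does their gut microbiome divert?
Answering that requires an energy ledger that host and microbes share.
`gutcod` keeps every flux in **chemical oxygen demand** (COD, grams of O2
to fully oxidize a material): COD is conserved across biological
conversions and measurable on both food and feces, so dietary intake,
fecal losses, microbial biomass, absorbed short-chain fatty acids (SCFA)
and methane all close one electron balance. The package is written for
researchers analyzing inpatient crossover feeding studies that compare a
fiber-rich, minimally processed "microbiome enhancer" diet (MBD) against a
processed Western diet (WD) under energy-balance control.

It provides, as pipeable data-frame-first functions:

* **Energy accounting** — macronutrients to substrate-class COD
  (`partition_substrates()`), host metabolizable energy
  `ME = 100 (COD_in - COD_fecal) / COD_in` (`host_me()`),
  non-metabolizable kcal, methane combustion energy, kcal/COD
  interconversion.
* **Marker normalization** — PEG3350 recovery and conversion of multi-day
  composite fecal collections into 24-hour outputs (`normalize_fecal()`).
* **Biomass quantification** — qPCR plasmid standards by mole arithmetic
  and 16S gene outputs to biomass gCOD/day (`plasmid_copy_number()`,
  `biomass_cod()`).
* **A three-compartment gut model** (`gut_predict()`) — upper-GI
  digestion (fractions `d_*`), colonic fermentation as a steady-state CSTR
  over the colonic transit time (extent `k tau / (1 + k tau)` per substrate
  class), fermented COD split into biomass / SCFA / methane
  (`y_biomass`, `a_scfa`, `f_ch4`), with an exact COD balance at every
  evaluation. Parameters ship calibrated against the study's six printed
  model outputs (`calibrate_gut_model()`, `scripts/calibrate-defaults.R`).
* **A synthetic crossover cohort** (`generate_cohort()`) — n participants
  by 2 diets with ground-truth latents (transit times, fermentation
  capacity, PEG recovery) and realistic assay noise, so the whole pipeline
  is testable without external data.
* **Crossover and agreement statistics** — paired within-participant
  effects, Bland-Altman limits of agreement, Lin's concordance,
  trapezoidal net iAUC, and a study report (`build_report()`), with
  broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods.

## Worked example

Run the calibrated gut model on the two arm-mean diets at a fixed 48-hour
colonic transit time:

```r
library(gutcod)
library(dplyr)

diet_templates() |>
  partition_substrates() |>
  gut_predict(ctt_h = 48) |>
  select(diet, me_pct, scfa_absorbed_total, biomass_fecal, fecal_total)
#> # A tibble: 2 x 5
#>   diet  me_pct scfa_absorbed_total biomass_fecal fecal_total
#> 1 WD      95.4                38.0          10.1        31.3
#> 2 MBD     92.1                82.6          21.8        58.0
```

The WD retains ~95.4 % of dietary electrons for the host; the fiber- and
resistant-starch-rich MBD diverts roughly twice the fecal COD and more
than doubles microbial biomass and absorbed SCFA.

Generate a full synthetic study (17 participants, both arms), run the
measurement pipeline, and compare measured against modeled ME:

```r
report <- cohort_config(seed = 42) |>
  generate_cohort() |>
  build_report()

tidy(report) |> filter(metric == "host metabolizable energy (%)")
#>   metric                        diet   mean   sem     n
#> 1 host metabolizable energy (%) MBD    89.6 0.452    17
#> 2 host metabolizable energy (%) WD     95.4 0.219    17

glance(report)
#>   ctt_mode   bias loa_low loa_high proportional_slope   ccc r_squared     n
#> 1 fixed     1.24    -2.58     5.05             -0.691 0.646     0.804    34
#> 2 measured -0.325   -2.35     1.70             -0.179 0.937     0.916    34
```

The pipeline recovers the arm means (89.6 % MBD, 95.4 % WD), and the model
agrees with the "measured" synthetic data far better when each
participant's transit time is used (concordance 0.94 vs 0.65): residence
time is the dominant driver of between-person differences in energy
harvest. `autoplot(report)`, `plot_ctt_sensitivity()` and
`autoplot(bland_altman(...))` draw the corresponding figures.

See `vignettes/gut-bioenergetics.Rmd` for the model's assumptions,
parameter meanings and defaults, the calibration procedure, and what the
synthetic cohort does and does not emulate.

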