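# milkwt

Plasma/milk pharmacokinetics and milk withdrawal-time estimation for
intravenous dosing studies in lactating animals.

When a veterinary drug is given to a lactating animal, two questions drive
the analysis of the resulting concentration–time data: *how does the body
handle the drug* (clearance, distribution volume, half-life), and *how long
must milk be withheld* before its residue concentration is reliably below
the regulatory maximum residue limit (MRL). `milkwt` implements the complete
pipeline for a two-period crossover IV-bolus study sampled in both plasma
and milk:

- **Non-compartmental analysis (NCA)** per profile: trapezoidal
  AUC/AUMC (linear or linear-up/log-down), automatic terminal-slope
  (λz) selection by best adjusted R² over candidate windows, extrapolation
  to infinity, and the derived set C0, Cmax, Tmax, AUC₀₋ₗₐₛₜ, AUC₀₋∞,
  AUC_extrap%, MRT₀₋∞, t½λz, Cl_T = dose/AUC₀₋∞, V_dss = Cl_T·MRT₀₋∞.
  Below-LLOQ (BLQ) samples are flagged, never substituted.
- **Milk penetration**: per-subject milk/plasma AUC ratios and
  time-matched concentration ratios, summarized by geometric means.
- **Withdrawal time (WT)**: all animals' quantifiable milk observations are
  pooled into one log-linear depletion regression
  ln C = a + b·t + ε, and the WT is the last time at which the upper
  one-sided tolerance limit

  U(t) = â + b̂·t + k(t)·s,  k(t) = √d(t) · t′_{df, z_p/√d(t)}(conf),
  d(t) = 1/n + (t − t̄)²/Sxx

  (the noncentral-t bound that covers the p-th percentile of an individual
  observation with confidence `conf`; defaults p = conf = 0.95) still
  reaches the MRL. Fractional estimates are reported rounded up to the next
  hour. At most seven distinct time points enter the regression; beyond
  that, explicit exclusions are required.
- **Dose comparison**: exact Wilcoxon signed-rank (paired crossover
  default) or rank-sum tests with full enumeration, mid-ranks for ties, on
  dose-normalized parameters.
- **Synthetic studies**: a generator calibrated to a reference tolfenamic
  acid study in lactating sheep — bi-exponential plasma disposition solved
  from (C0, t½λz, Cl_T, V_dss) targets, Bateman milk curves solved from
  (Cmax, Tmax, last-detection-time) targets, log-normal assay error and
  between-subject variability, LLOQ censoring — so every stage can be
  exercised and validated without external data.

## Worked example

```r
library(milkwt)

study <- simulate_crossover_study(seed = 42)   # 8 ewes, 2 & 4 mg/kg IV
tab   <- nca_table(study$data)
subset(summarize_nca(tab),
       matrix == "plasma" & parameter %in% c("c0", "t_half_lambda_z"))
#>    matrix dose       parameter n center   min   max        summary
#> 17 plasma    2              c0 8  14.66 12.00 20.80 geometric mean
#> 24 plasma    2 t_half_lambda_z 8   2.40  2.25  2.46 geometric mean
#> 27 plasma    4              c0 8  28.90 25.24 32.92 geometric mean
#> 34 plasma    4 t_half_lambda_z 8   4.07  3.78  4.27 geometric mean

fit <- wt_fit(study$data, dose = 2, mrl = 50)  # milk withdrawal, 2 mg/kg
summary(fit)
#> Withdrawal time, milk at 2 mg/kg (MRL 50 ug/kg = 0.05 ug/mL):
#>   WT = 2.28 h, reported 3 h (95%ile, 95% confidence)
#> Pooled depletion regression: ln C = -1.257 -1.073 t
#>   n = 52 (8 animals, 7 times), s = 0.2597, df = 50
#>   times used (h): 0.08, 0.17, 0.25, 0.5, 0.75, 1, 1.5
```

The reported WT of 3 h means: with 95% confidence, at 3 h after dosing at
least 95% of individual milk concentrations are below the 50 µg/kg MRL.
`plot(fit)` draws the pooled data, fitted line, tolerance limit and MRL.

Milk exposure is a small fraction of plasma exposure, and the dose increase
is detectably supra-proportional:

```r
pt <- penetration_table(tab)
geomean(pt$auc_ratio_inf[pt$dose == 2])   # 0.025
pl <- tab[tab$matrix == "plasma", ]
compare_doses(pl[pl$dose == 2, ], pl[pl$dose == 4, ], "auc_inf")
#> signed_rank_exact: statistic = 36, two-sided p = 0.007812 (n = 8, exact)
#>   parameter: auc_inf (dose-normalized); significant at 0.05: yes
```

A thin command-line wrapper with `simulate`, `nca`, `wt`, `compare` and
`pipeline` subcommands is installed under `inst/cli/milkwt`.

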