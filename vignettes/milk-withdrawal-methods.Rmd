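---
title: "Methods: non-compartmental analysis and tolerance-limit milk withdrawal times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-compartmental analysis and tolerance-limit milk withdrawal times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkwt)
```

## The problem

After an intravenous dose of a drug to a lactating animal, concentrations
are measured repeatedly in plasma and in milk. Three kinds of quantities are
wanted: the animal-level disposition parameters (clearance, distribution
volume, half-life), the extent of drug passage into milk, and a regulatory
**withdrawal time** (WT) — the earliest time after dosing at which milk can
be used because its residue concentration is, with high confidence, below
the maximum residue limit (MRL). `milkwt` implements all three stages plus a
calibrated simulator, for a two-period crossover design in which every
animal receives both a low and a high dose separated by a washout.

## Non-compartmental analysis

Each profile (one subject × matrix × dose) is analysed without assuming a
compartmental model.

**BLQ handling.** Samples below the lower limit of quantification (LLOQ,
0.04 µg/mL for the reference assay) carry only a censoring flag, never an
imputed value. The NCA drops them entirely, so the analysed series ends at
the last quantifiable time; the pre-dose time-0 sample is a control and is
excluded everywhere.

**Terminal slope.** λz is the negative slope of the least-squares line of
ln C on t over a terminal window. The automatic rule evaluates *every*
window that ends at the last quantifiable point, starts strictly after
Tmax and has at least `lambda_z_min_points` (default 3) points, and keeps
the one with the largest adjusted R². Two windows whose adjusted R² differ
by less than 10⁻⁴ are treated as tied and the longer one wins — this makes
the choice deterministic on noise-free data, where many windows are
numerically perfect. A `manual` rule accepts explicit window bounds so a
published fit can be reproduced. If no window has a negative slope, λz is
flagged non-estimable and the extrapolated quantities (AUC₀₋∞, MRT, Cl_T,
V_dss, t½λz) are reported missing while AUC₀₋ₗₐₛₜ, Cmax and Tmax survive.

**Areas.** The default integration rule is the linear trapezoid; the
`linear_up_log_down` option applies the log-trapezoid on strictly
decreasing intervals (exact for exponential decline) and falls back to the
linear rule on any interval touching a zero concentration. AUMC uses the
corresponding first-moment formulas. Tails are added as
`c_last/λz` and `c_last·t_last/λz + c_last/λz²`.

**The time origin.** The reference analysis defines C0 as the concentration
at the first post-dose sample (0.08 h), so the default `c0_policy =
"first_observed"` starts integration there; its AUC estimand is therefore
the area from 0.08 h. The alternative `"back_extrapolate"` reconstructs
C(0) by ln-linear extrapolation through the first two quantifiable points,
the conventional IV-bolus treatment whose estimand is the full area from
t = 0. The distinction matters: clearance defined as dose/AUC(0→∞) can only
be recovered under the second policy, because for a fast distribution phase
(α ≈ 3–4 h⁻¹) the 0–0.08 h head holds over 10% of the total area. The
package's parameter-recovery checks therefore use `"back_extrapolate"`,
while the default remains `"first_observed"` to mirror the reference
definition of C0. Both policies are exercised in the test suite.

**Summaries.** Parameters are summarized across subjects by the geometric
mean with the observed range, except Tmax, which (being a discrete sampled
time) is summarized by the median. Per-subject ratio parameters are formed
before averaging, so geometric-mean identities such as
geomean(dose/AUCᵢ) = dose/geomean(AUCᵢ) hold exactly.

## Milk penetration and dose comparison

Milk exposure is expressed as the per-subject ratio AUC₀₋∞(milk) /
AUC₀₋∞(plasma), summarized geometrically; time-matched milk/plasma
concentration ratios are computed only at times actually sampled and
quantifiable in both matrices — no interpolation, because the design
samples both matrices on the same nominal schedule.

Dose proportionality is tested on parameters normalized linearly to the
reference dose (`value · ref_dose/dose`). Because the design is a paired
crossover, the default test is the Wilcoxon signed-rank on within-subject
differences; the unpaired rank-sum test is available as a literal
alternative. Both tests are **exact by enumeration** — all 2ⁿ sign
assignments, or all C(nₐ+n_b, nₐ) group assignments, with mid-ranks for
ties — because at n = 8 the asymptotic approximation is unreliable and the
base-R implementation abandons exactness in the presence of ties. Two-sided
p-values are 2·min(lower tail, upper tail) capped at 1. Enumeration is used
up to n = 15 pairs (or 2·10⁵ combinations); beyond that a tie-corrected
normal approximation is applied and flagged as such.

## The withdrawal-time model

All animals' quantifiable milk observations for one dose are pooled into a
single regression of ln C on t — one tolerance-limit curve per dose, not an
average of per-animal fits. With n pooled points, mean time t̄ and time sum
of squares Sxx, the upper one-sided tolerance limit at time t is

U(t) = â + b̂ t + k(t) s,   k(t) = √d(t) · t′\_{n−2, δ(t)}(conf),
δ(t) = z_p / √d(t),   d(t) = 1/n + (t − t̄)²/Sxx,

where t′ is a noncentral-t quantile and s the residual SD. U(t) exceeds the
p-th percentile of an individual observation at t with probability exactly
`conf` — the property verified by Monte-Carlo in the test suite. Defaults
p = conf = 0.95 ("95th percentile with 95% confidence").

The WT estimate is the **supremum** of {t : U(t) ≥ ln(MRL)}, located by a
2048-point grid scan followed by bisection to 10⁻⁶ h. The supremum (rather
than the first crossing) matters because d(t) grows quadratically away from
t̄, so U(t) can in principle dip below the cutoff and re-cross; a premature
WT is thereby excluded. The search window defaults to four times the data
span, with an explicit error if U is still above the cutoff at its end.
The MRL (µg/kg) is converted to µg/mL through a configurable milk density
defaulting to 1.0 kg/L, making the unit assumption auditable
(50 µg/kg → 0.05 µg/mL). Reported WTs round the estimate up to the next
whole hour (configurable, e.g. to a 12 h milking interval); estimates
already on the grid are unchanged.

Two guard rails reflect the EMA-style workflow the construction follows:
at most `max_wt_time_points` (default 7) distinct sampling times may enter
the regression, and when the data exceed that cap the user must list the
times to exclude — the reference analysis dropped 0.17 and 0.75 h in its
high-dose arm without stating a rule, so the package refuses to invent one.
A non-negative pooled slope and an all-censored dataset are explicit
errors, and when the residual SD is zero the limit collapses onto the
fitted line, whose MRL crossing (ln MRL − â)/b̂ is then returned.

## The synthetic-study generator

The generator exists so the whole pipeline can be validated without the
study's unpublished raw data. Its defaults emulate the reference
conditions: 8 ewes, crossover 2 and 4 mg/kg IV, the nominal schedule
0 (control), 0.08, 0.17, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10,
12, 18, 24, 48 h, LLOQ 0.04 µg/mL.

**Plasma.** Disposition is bi-exponential, C(t) = A e^(−αt) + B e^(−βt):
the reported MRT (2.04 h at the low dose) is far below t½/ln 2 (3.48 h),
which rules out mono-exponential disposition. The four macro-constants are
solved, not hand-tuned, from the reported targets: β = ln 2/t½,
AUC = dose/Cl, MRT = V_dss/Cl, and C(0.08 h) = C0 — the last applied at
0.08 h because that is where the reference analysis defines C0 (with
A + B = C0 instead, the curve at 0.08 h would undershoot the target by
17%). Low dose: C0 13.30 µg/mL, t½ 2.41 h, Cl 0.21 L/h/kg, V_dss
0.43 L/kg; high dose: 31.77, 4.14, 0.13, 0.50 — the supra-proportional
exposure is reproduced by the per-dose calibrations, not mechanistically.
When two bi-exponentials satisfy the constraints the one with the slower
distribution phase is taken, deterministically.

**Milk.** Curves follow a Bateman shape M(t) = S(e^(−k_out t) −
e^(−k_in t)), the simplest form with a finite peak. The three parameters
are solved from the reported milk peak (Cmax 0.26 / 0.43 µg/mL at Tmax
0.25 h) and the reported end of the detection window (concentration equal
to the LLOQ at 1.5 h / 3 h). The milk terminal rate is therefore *not*
tied to the plasma β: with k_out = β the low-dose curve would stay
quantifiable until ≈ 6.8 h, contradicting the observed 1.5 h window and
pushing the WT far beyond the reported order of magnitude. The calibrated
k_out (≈ 1.7 and 0.9 h⁻¹) is a descriptive choice matching the observed
depletion, not a physiological claim; the complete-udder-emptying protocol
is not modelled.

**Variability.** Observations receive multiplicative log-normal assay
error, default CV 0.10, consistent with the assay's reported precision
(≤ 7.4–8.4%). Between-subject variability (default CV 0.10) multiplies the
amplitude constants (A, B, milk S) only: the reported half-life ranges are
tight (± ≈ 4%) while exposure ranges are wider (± ≈ 12%), so a common CV on
the rate constants would contradict them. Consequently simulated λz is
nearly constant across subjects while AUC, Cl and milk exposure vary. All
randomness flows from one root seed; the same seed reproduces a dataset
bit-for-bit. A zero pre-dose concentration makes the time-0 control row
BLQ by construction.

**What passing tests do and do not show.** The generator shares the
pipeline's structural assumptions (log-linear terminal decline, a single
pooled depletion line, symmetric multiplicative error). Tests passing on it
validate the arithmetic and the statistical construction, and the
simulation-based checks (clearance recovery within 15%, WT in a plausible
1–6 h band, exact-test level and power) validate behaviour *under those
assumptions* — they cannot detect model misspecification that real milk
data might show (milking-interval dynamics, nonlinear protein binding,
heteroscedastic assay error near the LLOQ).

## Numerical choices

- λz window ties: adjusted R² within 10⁻⁴ → longer window.
- Cmax/Tmax ties: earliest time wins.
- Calibration root-finding: `uniroot` at tolerance 10⁻¹²; the plasma solver
  scans 2001 bracket points for the first sign change; infeasible targets
  raise errors naming the violated constraint.
- WT crossing: 2048-interval grid + bisection to 10⁻⁶ h.
- Tolerance factor: `qt(conf, df, ncp)`; non-finite results are an error
  echoing the inputs rather than a silent NA.
- Exact-test tails use a 10⁻⁹ comparison slack so mid-ranks (half-integer
  statistics) are classified robustly.
- Time matching (exclusions, shared-time ratios) uses an absolute 10⁻⁹ h
  tolerance.

## Validation problem sizes

The shipped checks use: dense noise-free bi-exponential profiles of 800 to
1000 points over 0–48 h (≥ 10 terminal half-lives) against closed forms
(areas and derived parameters within 1%, λz within 0.5%); 10,000
Monte-Carlo replicates at n = 20 for tolerance-limit coverage (±0.01), plus
4,000-replicate checks at n = 10 and 56; 200 simulated studies for WT
plausibility; 1,000 dose-proportional studies for the exact test's type-I
error (the attainable exact size at n = 8 is 0.0391, slightly conservative
relative to the nominal 0.05 by discreteness) and 60 supra-proportional
studies for power; and full enumeration oracles for all Wilcoxon p-values
at n ≤ 8 including ties.

## Known limitations

- The WT model implements the pooled-regression noncentral-t tolerance
  bound only; variance-homogeneity pre-tests and outlier rules found in
  some regulatory software are out of scope, as are tissue withdrawal
  periods and Bayesian WT methods.
- Pooling treats every animal-time observation as exchangeable; no
  within-animal correlation structure is modelled.
- Normality/variance pre-tests of the dose comparison are deliberately not
  re-implemented; the nonparametric test runs unconditionally.
- The generator's supra-proportional high dose is phenomenological
  (separate calibration), so it cannot be used to study the *mechanism* of
  nonlinearity, only its consequences for the analysis stages.
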