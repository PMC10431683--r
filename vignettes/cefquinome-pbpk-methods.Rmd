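---
title: "Methods: a population PBPK model of intramuscular cefquinome in swine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a population PBPK model of intramuscular cefquinome in swine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceqpbpk)
```

## The problem

Cefquinome is a fourth-generation cephalosporin licensed for swine
respiratory disease at 1-2 mg/kg intramuscularly once daily. Two questions
drive this package. First, do the label dose and candidate extra-label
doses put enough *free* drug into the lung interstitial fluid (the biophase
of the extracellular respiratory pathogens) for long enough? For a
time-dependent beta-lactam the efficacy index is %T>MIC, the percentage of
the dosing interval during which the unbound concentration exceeds the
pathogen's MIC. Second, if a higher dose is used, how many days must
elapse before liver and kidney residues fall below their maximum residue
limits (MRLs), so that the food-safety withdrawal interval (WDI) can be
set?

Both questions concern population tails (90th percentile of efficacy,
99th percentile of residues), so a deterministic model is not enough: the
package couples a whole-body PBPK model to a Monte Carlo population layer.

## Model structure

The body is six compartments connected by blood flow: venous and arterial
blood, lung, liver, kidney, muscle, and a rest-of-body pool. Liver,
kidney, muscle and rest are perfusion-limited and well stirred,

$$\frac{dA_T}{dt} = Q_T \left(C_{art} - \frac{C_T}{P_T}\right),$$

with $Q_T$ the regional blood flow (L/h) and $P_T$ the tissue:blood
partition coefficient. The lung carries the entire cardiac output in
series (venous blood to lung blood to arterial blood) and is
permeability-limited, resolved into lung blood, interstitial fluid (IF)
and tissue sub-compartments exchanging only free drug. Plasma protein
binding is `PB` = 0.188 and lung tissue binding `PT` = 0.3; the IF is
taken as binding-free, which is what a microdialysis probe samples.

An intramuscular dose enters a two-pool depot: a fraction `Frac` = 0.1 of
each dose goes to a slow pool released at `Kdiss` = 0.05/h into the fast
pool, and the remainder to the fast pool, absorbed into venous blood at
`Kim` = 7/h. The opposite assignment (90% slow) would give an absorption
half-time of about 14 h, contradicting the observed early plasma peak, so
it is not used. Hepatic and renal elimination drain the
venous-equilibrated organ concentrations, $CL_{bile} \cdot C_L/P_L$ and
$CL_{urine} \cdot C_K/P_K$ with $CL = K \cdot BW$. Because the organ is
fed at $Q_T C_{art}$, this is the well-stirred extraction model: effective
plasma clearance is $Q_K CL_{urine}/(Q_K + CL_{urine})$ plus the small
hepatic term, which is why cardiac output and kidney flow carry
non-trivial sensitivity on plasma exposure.

The whole system is linear and time-invariant between dose events. The
implementation builds the coefficient matrix once (`pbpk_matrix()`) and
integrates with the stiff-capable `lsoda`, handing it the constant
analytic Jacobian and restarting at every dose event; relative tolerance
1e-8, absolute tolerance 1e-10 mg, default output grid 0.05 h. AUCs are
carried as additional ODE states, so they are exact integrals rather than
grid quadrature. In the tests, the same linear system is solved
independently through the matrix exponential and the two routes agree to
1e-5; mass balance (body + depots + urine + bile = administered) holds to
1e-6 relative at all output times.

One bookkeeping subtlety: the published fractional flows sum to 1.003, not
1. The arterial outflow is therefore set to the *sum of tissue inflows*
rather than to cardiac output; otherwise roughly 7% of the circulating
mass is created over five days and mass balance fails.

## The lung exchange formulation, and why it is a switch

The source model family does not publish its lung equations, only four
first-order constants: `KBI` = 0.110, `KIB` = 0.052 ("blood-IF" pair) and
`KIT` = 3.56, `KTI` = 2.60 ("IF-tissue" pair), all per hour. Taking the
labels literally (`lung_model = "amount"`: rates on free amounts, slow
pair at the blood-IF interface) produces an interstitial profile that
creeps up to ~0.3 ug/mL around 6 h and stays there - irreconcilable with
the microdialysis observations this compartment was calibrated against
(peak ~2.5 ug/mL at 1.25 h, elimination half-life 1.34 h, similar to
plasma) and with the published population dosage table, whose lung-IF
%T>MIC at MIC = 1 ug/mL is impossible if the IF never approaches
1 ug/mL. A slow pair of 0.05-0.11/h cannot carry the blood-IF exchange of
a compartment that tracks plasma within an hour, on any reading of the
units.

The package therefore defaults to `lung_model = "calibrated"`: transfer as
permeability clearances acting on free concentrations, with the fast pair
at the blood-IF interface (blood to IF at `KIT` on unbound lung-blood
concentration, IF to blood at `KTI`) and the slow pair at the IF-tissue
interface (uptake `KBI`, return `KIB` on the unbound tissue
concentration). At equilibrium the IF concentration is
$KIT(1-PB)/KTI \approx 1.11$ times total blood, so the simulated 24-h
IF:plasma AUC ratio is ~1.11 - modestly above the penetration ratio of
0.86 measured here, and inside the 0.9-1.6 range other swine
microdialysis studies report. This variant reproduces the deterministic dosage-table
values (e.g. 2 mg/kg once daily: free plasma %T>MIC(0.25) 19.8 vs the
published median 19.3; lung IF 23.3 vs 22.1, and 12.1 vs 13.4 at MIC 1).
Both formulations are kept behind the `lung_model` switch so the choice is
auditable.

A consequence worth stating plainly: with fast blood-IF equilibration the
lung-tissue binding fraction `PT` has essentially no leverage on the 24-h
IF AUC (its normalized sensitivity coefficient is ~0), whereas the source
reports -0.31 for it. A value of -0.31 requires a slowly equilibrating,
sequestering lung - the very behaviour the dosage table rules out. The two
published results are mutually inconsistent under any single formulation
we could construct; this package follows the dosage table and documents
the discrepancy rather than splitting the difference.

`PLU` = 1.5, the lung:blood partition coefficient, is also structurally
ambiguous. By default (`plu_mode = "report"`) it scales only the reported
equilibrium whole-lung concentration ($PLU \cdot C_{lung\,blood}$) and
does not enter the kinetics - matching the published sensitivity pattern,
where `PLU` moves the lung AUC but is absent from the IF sensitivity
list. The alternative (`plu_mode = "tissue_partition"`) uses it as the
tissue:IF partition inside the exchange.

## Microdialysis calibration and NCA

Probe calibration is plain arithmetic: in vitro recovery
$100 \cdot C_{dial}/C_{medium}$, retrodialysis delivery
$100 (1 - C_{dial}/C_{perf})$, in vivo relative recovery
$100 (C_{perf}-C_{dial})/C_{perf}$, and the ISF correction
$C_{ISF} = C_{dial}/RR$. The NCA uses the linear trapezoid to the last
quantifiable point (no extrapolation unless asked; the published AUC does
not state whether it extrapolates, which is an open point), and selects
the terminal window among the last 3-5 quantifiable points by maximal
adjusted R^2 of the log-linear fit - the software used by the source
study applies a comparable default. Observations below the LLOQ
(0.05 ug/mL) are treated as missing.

## Calibration metrics and fitting

`r_squared()` is $1 - SS_{res}/SS_{tot}$ against the observed mean (1 for
perfect prediction, 0 for mean-level prediction), `mape()` the mean
absolute percentage error with the conventional <10 / <20 / <50%
excellent/good/acceptable bands, and `twofold_fraction()` the WHO-style
share of predictions within twofold of observation. `fit_parameters()`
wraps bounded Levenberg-Marquardt least squares on log-scale residuals
(residue data span orders of magnitude), equal weight per observation,
sub-LLOQ points excluded. The finite-difference step of the numerical
Jacobian is held well above the ODE solver tolerance; otherwise the
optimizer differentiates integrator noise and stalls a few percent from
the optimum. On noise-free synthetic data the identifiable set
{KurineC, PLU, KTI} is recovered to well under 1%.

## Sensitivity analysis

`nsc()` is the forward-difference normalized sensitivity coefficient at
+10%: $NSC = \frac{\Delta AUC / AUC}{\Delta p / p}$ over a 24-h horizon
(a central difference is available). The screen covers 31 scalar inputs -
every tabulated parameter except the balancing remainders `QRC` and
`VRC` - against the AUCs of plasma, liver, kidney, muscle, lung and lung
IF; |NSC| > 0.25 flags influence. When a flow or volume fraction is
perturbed, its remainder (`QRC`, `VRC`, or `VLUT`) absorbs the change, so
the perturbation redistributes flow rather than silently altering total
venous return; without this the recirculation offset masks about half of
a flow parameter's true effect. The source text states the perturbation
as "p/Δp = 10%", which contradicts its own "increasing each parameter by
10%"; the latter is implemented.

## Population layer

Eleven influential parameters are sampled: cardiac output and kidney flow
fraction as truncated normals (CV 0.3), partition coefficients as
truncated lognormals (CV 0.2), lung transfer constants, renal clearance
and lung tissue binding as truncated lognormals (CV 0.3). Lognormals are
parameterized so that the stated mean is the natural-scale arithmetic
mean: $\sigma^2 = \ln(1+CV^2)$, $\mu = \ln(mean) - \sigma^2/2$. This is
the only parameterization that reproduces every published 2.5th/97.5th
truncation bound to the printed 0.01, which is the one available check.
Draws outside the bounds are rejected and redrawn - clipping would put
probability atoms on the bounds. Flows are deliberately not renormalized
after sampling the kidney flow fraction (the rest-of-body share stays at
its mean), a documented caveat of the sampling design. Percentiles are
empirical linear-interpolation order statistics (`quantile` type 7); with
1000 individuals the 99th percentile rests on the top dozen draws, so the
estimator choice is stated rather than hidden.

Note an asymmetry this parameterization implies: the *median* of a
lognormal with fixed arithmetic mean is $mean/\sqrt{1+CV^2}$, about 4%
below the mean at CV 0.3. Population medians of exposure metrics
therefore sit slightly above the deterministic run (which uses the means),
and the simulated dosage-table medians inherit that shift.

## Dosage evaluation and withdrawal intervals

`time_above_mic()` integrates the indicator of free concentration above
MIC treating the trace as piecewise linear, so crossing times are refined
by interpolation and the result is exact for the stored grid. Free plasma
is the unbound arterial concentration $(1-PB) \cdot C_{art}$; lung IF is
free by construction. The evaluation window is the first 24-h dosing day
(doses at 0 h, or 0 and 12 h for twice-daily), and percent is always
relative to 24 h so the two schedules are comparable; the published table
does not state first-day versus steady state, and first-day is the
parsimonious reading for a drug with a ~1 h half-life. Each schedule's
Monte Carlo cells share one random stream across dose levels (common
random numbers), so tabulated percentiles are monotone in dose exactly as
the linear kinetics imply. `pta()` reports the fraction of individuals
meeting a %T>MIC target.

Residue depletion simulates total liver and kidney concentrations
(`ug/g` at unit tissue density) for multi-day regimens; the twice-daily
extra-label course is read as 5 days x 2 doses (10 doses, 12 h apart),
with the single-table alternative available by constructing the regimen
directly. The WDI is the smallest whole day after the last dose at which
the empirical 99th percentile is at or below the MRL (liver 0.1, kidney
0.2 ug/g) in both tissues at once - the slaughter-day convention on a
24-h grid. The MRL assignment follows the regulatory limits (liver 0.1,
kidney 0.2); one figure caption in the source swaps the two tissues, and
the swapped reading is not used.

## Synthetic data

`generate_study()` emulates the study designs the real model was
calibrated against: single-dose plasma profiles, five-day liver/kidney
residue-depletion designs, and the 14-point dialysate schedule of the
lung microdialysis experiment (`dialysate_sampling_times()`). Per animal,
parameters are drawn from the population distributions, the model is
simulated, sampled at the design times, multiplied by mean-1 lognormal
assay noise (default CV 0.20), and censored at the LLOQ. The generating
truth is attached so parameter-recovery experiments close the loop. What
passing on such data shows is internal consistency - that the estimation
machinery recovers the generating process; it cannot show that the model
matches real pigs, which requires the external datasets that are out of
scope here.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 1000-individual
populations for the dosage and withdrawal endpoints (matching the study
design), 24-h dosing-day simulations on a 0.05-h grid, and residue
horizons of last dose + 6 days on a 0.5-h grid; smaller ensembles are
used for structural property checks where only ordering matters. A
single 24-h individual solves in ~15 ms, so the full acceptance
recomputation is a few minutes of one core. Dose events restart the
integrator exactly; at a dose time the reported state is the pre-dose
trough. Solver warnings (e.g. truncated early returns under extreme
parameter draws) are escalated to errors, and the population layer
resamples such draws, counting them in the ensemble report.

## Known limitations

- The lung exchange formulation is a reconstruction; its equations are
  chosen by calibration against published outputs, not transcribed. The
  `lung_model` switch preserves the literal alternative.
- The reported lung-tissue binding sensitivity (-0.31) cannot be
  reproduced jointly with the dosage table; see above.
- Fixed 25-kg body weight; no allometry, no covariates, no
  inter-parameter correlation in the population layer.
- No enterohepatic recirculation, metabolites, or non-IM routes.
- The WDI uses empirical percentiles, not the regression-based
  tolerance-limit algorithm some regulators prescribe; that would be an
  extension, not a patch.
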