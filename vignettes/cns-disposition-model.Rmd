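---
title: "Methods: the CNS steady-state disposition model and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CNS steady-state disposition model and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpuuCNS)
```

## The scientific problem

Efflux transporters MDR1 (P-glycoprotein) and BCRP at the blood–brain
barrier (BBB) extrude many drug candidates back into the circulation,
lowering the unbound brain-to-plasma concentration ratio
$K_{p,uu,brain}$. Because human brain sampling is rarely possible, CSF
concentration is the accessible clinical surrogate — but the unbound
CSF-to-plasma ratio $K_{p,uu,CSF}$ is systematically higher than
$K_{p,uu,brain}$ for efflux substrates. A model that predicts **both**
quantities from in vitro data alone lets a project team estimate human
brain exposure, and judge when CSF is a faithful surrogate, before any
in vivo CNS study.

## Model structure and assumptions

Unbound drug distributes at steady state among plasma (concentration
fixed at 1, so the compartment solutions *are* the partition
coefficients), brain extracellular fluid, and CSF, connected by:

| Clearance | Meaning | Form | Units |
|---|---|---|---|
| `PS1` | passive BBB permeability–surface area product | $\frac{3600}{1000} X\,10^{0.182(\log D - 0.5\log_{10} MW) - 1.86}$ | L/h/kg |
| `PS2` | brain–CSF exchange (ependymal layer) | $PS_1/\sigma$ | L/h/kg |
| `PS3` | passive blood–CSF barrier clearance | $PS_1/\gamma$ | L/h/kg |
| `PS4` | MDR1/BCRP active efflux at the BBB | $f(\mathrm{ERs})\cdot PS_1$ | L/h/kg |
| `CL_bulkflow` | CSF bulk-flow sink | species constant | L/h/kg |

with $f(\mathrm{ERs}) = \alpha(ER_{MDR1}-1) + \beta(ER_{BCRP}-1)$.

Assumptions worth stating explicitly:

- **Steady state only.** No time course is modeled; observed data must
  come from infusion-to-steady-state or equivalent designs.
- **Efflux only at the BBB.** The choroid plexus (blood–CSF barrier) is
  treated as purely passive plus the bulk-flow sink; MDR1/BCRP at the
  BCSFB are neglected. Only these two transporters are considered.
- **Proportional passive clearances.** Brain–CSF and BCSFB passive
  clearances are tied to `PS1` through the fitted structural ratios
  $\sigma$ and $\gamma$ rather than modeled independently. The
  ependymal layer is treated as barrier-free surface, so $\sigma$
  absorbs the geometry, and brain total concentration is assumed to be
  governed by the same membrane-permeation process that `PS1`
  describes.
- **Efflux ratios transfer across species.** One human-transporter MDCK
  assay feeds all species; species differences in in vivo activity are
  carried entirely by $\alpha$ and $\beta$.

The closed forms for $K_{p,uu,brain}$ and $K_{p,uu,CSF}$ (see
`?predict_kpuu_brain`) share a denominator and are algebraically
equivalent to the 2×2 linear steady-state solve implemented
independently in `steady_state_kpuu()`. The package treats that solver
as the structural oracle: the test suite checks agreement to better
than $10^{-10}$ relative over 1000 random admissible parameter draws,
which pins down the implementation of both routes.

### Reading of the PS1 correlation

The source literature for the passive-permeability correlation typesets
the exponent ambiguously. We adopt the reading
$0.182\,\log_{10}(D/\sqrt{MW}) - 1.86$ with
$\log_{10}(D/\sqrt{MW}) = \log D - 0.5\log_{10} MW$, in mL/s/g brain,
converted by $3600/1000 \times X$ (brain weight, g/kg body weight) to
L/h/kg. This is the only reading that makes the published conversion
factors dimensionally coherent and keeps `PS1` increasing in logD,
decreasing in MW, and linear in brain weight. Similarly, published
`PS2`/`PS3` expressions carry residual unit-conversion factors
(·60/1000) that are algebraically incompatible with the closed forms;
the mass-balance derivation requires exactly $PS_2 = PS_1/\sigma$ and
$PS_3 = PS_1/\gamma$, which is what the package uses and what the
oracle-equivalence test enforces.

### Efflux ratios below one

$f(\mathrm{ERs})$ would go negative for $ER < 1$, turning "efflux" into
uptake. Each $(ER-1)$ term is floored at zero: sub-unity efflux ratios
are assay noise or weak uptake, and the model's active term represents
efflux only. The floor also keeps the predictions within (0, 1], which
the bound test asserts numerically.

### Limits

With $1/\sigma \to 0$ the brain equation collapses to the brain-only
simplification $K_{p,uu,brain} = 1/(1+f(\mathrm{ERs}))$, and the
CSF/brain ratio to the two-term approximation in
`kpuu_ratio_approx()`. `sigma = Inf` and `gamma = Inf` are accepted and
evaluated as analytic limits (the $\gamma=\infty$ branch divides
through by $\gamma$ first) rather than producing `Inf/Inf`.

## Parameters

| Parameter | Meaning | Units | Built-in values |
|---|---|---|---|
| $\alpha$ | in vitro → in vivo MDR1 activity scaler | – | RAF: 0.395 / 0.126 / 0.096 (rat/monkey/human); REF: 0.240 / 0.059 / 0.077 |
| $\beta$ | in vitro → in vivo BCRP activity scaler | – | RAF: 1.368 / 0.638 / 2.054; REF: 0.437 / 1.248 / 0.716 |
| $\gamma$ | BBB : BCSFB passive permeability ratio | – | 1910 / 1853 / 1468 |
| $\sigma$ | BBB : ependymal-layer permeability ratio | – | 1054 / 530 / 967 |
| $X$ | brain weight | g/kg | 7.2 / 18 / 20 |
| $CL_{bulkflow}$ | CSF bulk flow | L/h/kg | 0.000528 / 0.000492 / 0.000300 |
| $Q_{alb}$ | CSF:plasma albumin ratio | – | 0.003 / 0.002 / 0.005 |

$\gamma$ and $\sigma$ are structural, so the REF registries reuse the
RAF-fitted values per species. The physiology rows are fixed constants,
never fitted.

## Estimation

`fit_kpuu()` minimizes the pooled sum of squared $\log_{10}$ residuals
over both endpoints, weighted equally (the two endpoints are fitted
*simultaneously*; a record missing one endpoint contributes only the
other). Choices:

- **Log-space search.** The objective is optimized over
  $\log_{10}(\alpha,\beta,\gamma,\sigma)$ with bounded L-BFGS-B:
  the parameters are positive and span four orders of magnitude, so log
  space gives comparable step sizes in every direction. Bounds default
  to $\alpha,\beta \in [10^{-6}, 100]$ (the lower bound is the
  practical zero of the log scale) and $\gamma,\sigma \in [1, 10^6]$.
- **Multistart.** 32 starts — the midpoint of the log-bounds box plus
  31 log-uniform draws under a fixed seed — guard against local optima;
  the best optimum is kept and `multistart_best_of` records the count.
  The fit is a deterministic function of (data, seed), and the caller's
  RNG state is left untouched.
- **Uncertainty.** Standard errors come from the Gauss–Newton
  approximation at the optimum: numeric central-difference Jacobian
  $J$ of the residual vector with respect to the *raw* parameters,
  $\widehat{\mathrm{cov}} = \hat s^2 (J^\top J)^{-1}$ with
  $\hat s^2 = RSS/(n-4)$, and %CV $= 100\,SE/\hat\theta$. Flat
  directions (γ, σ with few low-permeability compounds) legitimately
  produce %CV above 100; that mirrors the uncertainty reported for the
  built-in sets. A singular $J^\top J$ yields `NA` SEs rather than an
  error.
- **Identifiability.** Fewer than four observed endpoints, or a dataset
  whose efflux ratios are all ≤ 1 (so $f(\mathrm{ERs}) \equiv 0$),
  raises an identifiability error instead of returning arbitrary
  $\alpha,\beta$.

## REF calibration

Relative expression factors from proteomics apply on the efflux-ratio
scale of the laboratory that measured them. `calibrate_ref()` regresses
internal on literature efflux ratios of shared scaler compounds
(prazosin, quinidine, metoprolol, pitavastatin) per cell line with the
intercept fixed at zero — a pure rescaling, which is all a one-factor
calibration can support — and divides the reported REF by the slope so
it applies on the internal scale. The direction and intercept
convention are not standardized in the field, so both are explicit
arguments (`direction = "divide"`/`"multiply"`). Only calibrated REF
values ship as built-in constants.

## Accuracy statistics

AFE ($10^{\overline{\log_{10}(pred/obs)}}$, bias), AAFE (absolute
version, accuracy), RMSE on the linear scale (precision), and the
3-fold classification. Boundary ratios of exactly 3 or 1/3 count as
*within* the band by default (`inclusive = TRUE`); the convention is
configurable because the field reports it inconsistently. Percentages
are integer-rounded for table display with raw fractions kept as an
attribute. `compare_raf_ref()` runs paired two-sided t-tests
(α = 0.05) on per-compound log fold errors, absolute log fold errors,
and squared residuals; all-zero differences report *no difference*
(p = 1), while a constant nonzero difference (zero variance) is
reported as $t=\pm\infty$, p = 0.

## The synthetic compound generator

`simulate_compounds()` emulates the statistical structure of a CNS
discovery compound set: logD uniform on $[-2, 5]$, MW log-uniform on
$[150, 700]$ g/mol, efflux ratios log-uniform on $[0.3, 50]$ — ranges
spanning marketed CNS and non-CNS drug space — with optional
stratification of the fraction of MDR1 (ER ≥ 6.0) and BCRP (ER ≥ 2.5)
substrates. Observed $K_{p,uu}$ values are the model's own predictions
multiplied by independent log-normal noise; the log10-scale SD is
$\log_{10}(\mathrm{AAFE})\sqrt{\pi/2}$ so the expected AAFE equals the
requested level (for $X \sim N(0,s^2)$, $E|X| = s\sqrt{2/\pi}$). The
default noise AAFE of 2 matches the accuracy level typical of
cross-species $K_{p,uu}$ prediction.

What the generator does **not** emulate: correlation between
lipophilicity, binding, and efflux liability found in real chemistry;
assay-specific heteroscedasticity (CSF noise growing near the
quantification limit); inter-laboratory systematic shifts; or any real
compound's identity. Passing generate-then-refit tests therefore
demonstrates that the estimator is correct and well-conditioned under
the model's own assumptions — not that the model is true of any
particular chemical series.

## Problem sizes and numerical tolerances

The validation studies use 60 compounds per dataset (the order of a
single-species in vivo dataset in this field), 20 noisy replicates for
recovery medians, 1000 random draws for the oracle-equivalence check at
$10^{-10}$ relative tolerance, and $10^4$ draws to verify the noise
calibration within 2%. Noiseless recovery is expected to within 1%
(α, β) and 10% (γ, σ — flat directions); noisy recovery medians to
within ±50%. These sizes make the whole suite run in seconds while
leaving each check far from its tolerance boundary.

## Known limitations

- Steady state only; no prediction of time to attain it.
- Two transporters; compounds handled by OAT/OATP/MATE or extensively
  metabolized in brain will be mispredicted.
- CSF sampling-site gradients (cisterna magna vs lumbar) are not
  corrected; observed $K_{p,uu,CSF}$ from different sites carry that
  heterogeneity into the fit.
- The PS1 correlation is an empirical lipophilicity/size relation;
  compounds outside its calibration space (MW ≫ 700, zwitterions with
  atypical permeability) inherit its error directly.
- γ and σ are only weakly identified by datasets rich in
  high-permeability compounds; expect large %CV there, and prefer
  datasets that include low-permeability, high-efflux compounds.
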