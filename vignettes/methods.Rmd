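---
title: "A CNS and brain-tumor PBPK model with handshake estimation of blood-tumor-barrier pathophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A CNS and brain-tumor PBPK model with handshake estimation of blood-tumor-barrier pathophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btbpk)
```

## The problem

Malignant brain tumors disrupt the blood-brain barrier (BBB) into a leakier
blood-tumor barrier (BTB), but the two properties that control unbound drug
exposure in tumor extracellular fluid (ECF) — the paracellular pore size of
the BTB and the activity of active efflux transporters at it — are rarely
measured. `btbpk` implements a physiologically based model of drug transport
into brain and brain tumor, and a two-stage estimation workflow (the
"handshake") that extracts those two quantities, as fold changes over the
control-brain BBB, from unbound concentration-time data of the kind
microdialysis studies produce.

## Model structure

The CNS model has nine compartments: brain microvascular (MV) plasma, brain
ECF, brain intracellular fluid (ICF), brain cell membrane, lysosomes, and
four cerebrospinal-fluid (CSF) compartments (lateral ventricles, third +
fourth ventricles, cisterna magna, subarachnoid space). Plasma is an
empirical forcing function (one- or two-compartment, optional first-order
absorption with lag). The tumor extension inserts five further compartments
(tumor MV, ECF, ICF, membrane, lysosomes) between plasma and the lateral
ventricles, with the same internal structure as the brain side. Because no
spatial relation between tumor and sampled brain tissue is assumed, there is
no direct tumor-ECF to brain-ECF exchange; tumor ECF bulk flow drains into
the lateral-ventricle CSF compartment.

All transport is linear mass action. Between MV plasma and ECF, drug crosses:

* **paracellularly**, with clearance
  $CL_p = (D_{aq}/w)\,SA\,f_{pore}^{areal} \cdot 60 / \mathrm{corr}$,
  where $D_{aq} = 9.9\times10^{-5}\,MW^{-0.453}$ cm²/s is the aqueous
  diffusivity, $w$ = 0.5 µm the barrier width, $SA$ the barrier surface
  area, $f_{pore}^{areal} = 10^{-4}$ the areal fraction of paracellular
  pores, and `corr` the paracellular-permeability (PPA) correction factor
  (a fold-decrease, default 1);
* **transcellularly**, with clearance $CL_T = P_0\,SA \cdot 60 \cdot
  \mathrm{PHF}$, where $\log_{10} P_0 = 0.939\,\log P - 6.21$ (cm/s) and
  PHF is the donor-side unionized fraction from monoprotic
  Henderson-Hasselbalch partitioning — only the neutral species crosses
  membranes, so acidic tumor ECF (pH ~6.8-7.2) raises the outward pH factor
  of acids.

Active transport is represented by asymmetry factors (AF) multiplying the
passive transcellular clearances; exactly one of AF\_in, AF\_out exceeds 1.
They are derived from a measured steady-state unbound ECF partition
coefficient by inverting the closed form

$$K_{p,uu,ECF} = \frac{CL_p + AF_{in} CL_{T,in}}
{CL_p + AF_{out} CL_{T,out} + CL_{ECF}}$$

(`af_from_kpuu()`, `steady_state_kpuu()`). The membrane, ICF and lysosome
compartments form a dead-end chain whose fluxes cancel at steady state, so
they do not enter this ratio; lysosomal pH trapping and membrane
partitioning ($K_{mem} = 10^{\log P}$) only shape the kinetics.

The diffusivity and permeability correlations above, and the absolute
surface areas, CSF volumes and flows, membrane geometry (cell radius 5 µm,
cell surface area $3 V_{ICF}/r$), microvascular pH 7.4 and lysosomal pH 5.0
are versioned package fixtures (`default_physiology()`,
`transport_constants()`): plausible, overridable defaults rather than
measured constants. Every property-style test in the package holds for any
positive parameterization; only printed-number checks rely on the pinned
defaults.

## Tumor parameterization

Tumor records (`tumor_pathophysiology()`) carry the five parameters for
which literature values exist — tumor volume, volume fractions of MV and
ECF, extracellular and intracellular pH, and blood flow — with three
derivation rules implemented and tested against the bundled parameter table:
arithmetic means of literature values rounded to three significant figures
(halves away from zero, `signif_half_up()`), scaled means for known
vascularization multiples, and relative-to-control values multiplied by the
healthy reference. Everything else (microvascular and lysosomal pH, membrane
and lysosome fractions, ECF bulk flow per mL, cell radius) is inherited from
healthy physiology by `fill_healthy_defaults()`. BTB surface area scales the
BBB value by the tumor/brain microvascular volume ratio.

## The handshake workflow

**Stage 1** (`estimate_ppa_correction()`) fits the PPA correction factor to
control-brain ECF data by minimizing the sum of squared log10 residuals over
log-spaced starts. When the spec carries a measured control
$K_{p,uu,ECF}$, the AFs are re-derived for every candidate correction, so
the steady-state extent stays pinned to the measurement and the correction
is identified from the kinetics (time of peak, rate of approach). This is
also why the correction is practically estimable only for drugs with a
substantial paracellular share: for transcellular-dominant drugs the
correction barely moves the profile, and the workflow keeps a correction of
1 for them — both behaviors mirror the published analyses this model family
comes from.

**Stage 2** (`estimate_fold_changes()`) estimates the two BTB fold changes
simultaneously from tumor ECF data with the same log-SSE objective, from a
4 × 4 multi-start grid (log-spaced in the pore fold, signed in the efflux
fold). Two readings are pinned here:

* the pore-size fold multiplies the paracellular clearance **linearly**
  (slit-pore geometry: areal fraction proportional to pore width at fixed
  junctional length); a quadratic cylindrical-pore option is available via
  `transport_constants(pore_scaling = "quadratic")`;
* the efflux fold scales the **active component beyond passive**,
  $A = (AF_{out}-1)CL_{T,out}$: a fold of 1 preserves control transport, 0
  abolishes it, and negative values reverse it to net active influx. This is
  the only reading under which a negative estimate and "completely
  diminished efflux" are simultaneously coherent; it is an interpretation,
  not an established fact.

**Identifiability.** Tumor ECF data carry essentially two observables: the
quasi-steady-state tumor/plasma ratio (set by the inward/outward clearance
ratio) and the equilibration rate (set by the outward clearance over the
effective tumor volume, damped by perfusion extraction). For
paracellular-dominant drugs the equilibration is much faster than the plasma
kinetics, the rate is unobservable, and only the ratio of the two fold
changes is determined — an estimation ridge. The estimator operationalizes
the resulting "varied estimates depending on initial parameters" by running
limited-effort local searches from every start and reporting their relative
dispersion (`start_dispersion`, ridge flag above 0.10); only the best start
is then polished into the reported estimate. Fixing one parameter to 1
(`fix =`) reproduces the separate-estimation protocol for ridge cases.

## Synthetic studies

`generate_study()` emulates the statistical structure of microdialysis
studies: per subject, exponential inter-individual variability on plasma
clearance and central volume, simulation of the true control and tumor
models, interval-averaged sampling (trapezoid time-average over dialysate
collection bins; 20-min bins over 0-360 min by default, the typical
collection scheme of the source studies — actual schedules are not
published), proportional(/additive) residual error, and censoring at the
LLOQ. Probe recovery/calibration is assumed ideal (relative recovery 1),
because the model's inputs are already unbound ECF concentrations. What the
generator does **not** emulate: model misspecification (the estimation model
is the generating model), within-tumor heterogeneity, drift in barrier
properties over the experiment, and correlated residuals — so passing
recovery tests demonstrate estimator correctness under the stated
assumptions, not robustness on real data.

The recovery experiments in the test suite use two designs chosen to match
what each stage can identify: fold-change recovery uses a strongly effluxed,
moderately lipophilic neutral probe compound (logP 1, control
$K_{p,uu}$ 0.1, PPA correction 14) in a rat glioma setting, where tumor
equilibration (half-time ≈ 6 min) leaves both rate and extent observable;
correction-factor recovery uses a methotrexate-like acid with 12-point
sampling. Problem sizes (6 subjects, 18 bins, 20 replicates) keep the whole
suite in the minutes range while leaving the medians stable.

## Evaluation tools

`vpc()` runs 200 (default) stochastic replicates with IIV and residual error
and summarizes the pointwise median and 95% prediction interval, with
percentiles by linear interpolation between order statistics (R quantile
type 7; the alternative nearest-rank convention differs negligibly at 200
replicates). `relative_accuracy()` implements the mean log10 ratio of
matched median prediction to observation, excluding censored and
non-positive observations with a reported count, plus the fraction within
twofold. `sensitivity_scan()` perturbs one named parameter over a grid and
reports ECF C\_max, its time, and trapezoidal exposure.

## Numerical choices

* Plasma models are solved in closed form by eigen-decomposition of the
  linear rate matrix with superposition over dose events; an exact
  degenerate-rate guard perturbs the absorption constant by 1 part in 10⁸
  if it collides with a disposition eigenvalue.
* The CNS/tumor system is integrated with `deSolve::lsoda` (stiff-capable)
  and a constant analytic Jacobian, rtol 1e-8 / atol 1e-10 by default.
* The estimators evaluate the same model through the exact
  eigen-decomposition of the joint plasma-tissue system (block-triangular,
  so the forcing propagates analytically); this agrees with the ODE route
  to ~1e-10 relative and is two orders of magnitude faster. If the
  eigenvector basis is ill-conditioned the estimator falls back to stiff
  integration.
* Mass balance is tracked by cumulative-inflow/outflow bookkeeping states
  and closes to machine precision; the test suite enforces 0.1%.
* Objective: sum of squared log10 residuals, a scale-free proxy for the
  proportional-error likelihoods used in the original mixed-effects fits,
  appropriate across the thousand-fold concentration ranges involved.
  Observations at or below the LLOQ are excluded.
* Interval-mean predictions use a 4-sub-interval trapezoid per bin — the
  same rule in the generator and the estimators, so no discretization bias
  enters recovery tests.

## Known limitations

* Paracellular transport ignores charge, hydrodynamic (Renkin) sieving and
  tortuosity; these are the likely physical content of the estimated PPA
  correction factors, not separately resolved here.
* BCSFB active transport is passive (AF = 1) — no transporter data exist
  for it; the BCSFB paracellular clearance is split evenly between the
  lateral-ventricle and third/fourth-ventricle compartments.
* The PPA correction divides the BBB paracellular clearance only, not the
  BCSFB's, following the control-brain fitting protocol.
* Single tumor-core compartment: no peritumoral rim, no
  non-contrast-enhancing region, no spatial gradients.
* Plasma fitting is pooled maximum likelihood with per-subject refits for
  IIV — a deliberate substitute for the original NONMEM mixed-effects
  machinery, adequate for the synthetic-data workflows here.
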