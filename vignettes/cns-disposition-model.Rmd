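---
title: "Modeling ondansetron CNS disposition under P-glycoprotein modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ondansetron CNS disposition under P-glycoprotein modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnspk)
```

## The system and the model

Ondansetron is a P-glycoprotein (Pgp) substrate. At the blood–brain barrier
Pgp pumps it back into blood, so CNS exposure in a normal animal is a tug of
war between passive permeability and active efflux. The package models a rat
study design in which that efflux is switched off two ways — genetic knockout
(KO) and co-administration of the inhibitor tariquidar (the OT condition) —
against the wild-type (WT) reference, after a 10 mg/kg IV bolus.

The structural model is linear and semi-physiological: central and
peripheral systemic compartments plus brain, spinal cord and CSF, connected
by first-order rate constants, with the CNS tissue volumes fixed at measured
physiological values (brain 1.8 mL, spinal cord 0.6 mL, CSF 0.25 mL — fixed,
never estimated, because amounts and concentrations would otherwise be
confounded). Pgp efflux is one first-order constant `kPgp` carrying drug from
both brain and spinal cord back to the central compartment; using a single
shared constant for both tissues is a structural assumption of the model, not
a fitted simplification. CSF exchanges with both tissue compartments under
the tied parameterization `k35 = k45`, `k53 = k54`.

Group covariates act on the shared vector: KO sets `kPgp = 0`; OT replaces
the central volume and elimination constant with `V1_TRQ` and `kel_TRQ`
(tariquidar alters systemic disposition in a way that is apparently not
Pgp-mediated, since KO animals show no such shift) and replaces `kPgp` with a
residual `kPgp_TRQ`. Tariquidar itself is not modeled kinetically: its
half-life is long relative to the ondansetron experiment, so its presence is
a categorical covariate. A concentration-dependent (sigmoid) inhibition
function is deliberately out of scope for the same reason — the design
carries no information to support one.

## Units, dosing, defaults

Amounts are µg, volumes mL, times h, concentrations µg/mL throughout. Doses
convert from the mg/kg level via body weight; the defaults (0.325 kg male,
0.265 kg female) are midpoints of the study's weight ranges, giving 3250 and
2650 µg boluses. The packaged parameter files carry the final-model
estimates per sex; a few entries (`k_15`, `k_51`, `var_P`, `k_Pgp,TRQ`) are
flagged provisional because the printed source runs digits of the estimate
and its CV% together and the split is ambiguous. The alternative splits
change the simulated fold-change results by less than 1e-4.

## Simulation backends

The system is linear, so the default simulator propagates it exactly:
eigendecomposition of the 5×5 disposition matrix, with the cumulative
eliminated amount obtained by analytic integration of the central amount so
that mass balance is a genuine, independently computed check (the state sums
to the dose to ~1e-13 relative). A stiff ODE backend (`lsoda`, rtol 1e-8,
atol 1e-10 µg) is exposed as `method = "lsoda"`, serves as the automatic
fallback when the eigenvector matrix is ill-conditioned (condition number
above 1e12), and doubles as the independent cross-check route in the test
suite; the two agree to ~1e-8 relative on the study's parameter ranges. Rate
constants beyond 1e6 /h are rejected outright rather than fed to either
backend. The IV bolus is an initial condition at the dose time, not a short
infusion.

## Noncompartmental analysis

`auc_trapezoid()` defaults to the linear trapezoid — the conservative choice
where the original software's rule is unknown — with log-linear-down as an
option; the difference between the two is itself testable. The terminal
slope uses the last 3 points by default (configurable; best-r² automatic
selection available), requiring at least 3 positive concentrations and a
genuinely declining tail. Extrapolation to infinity uses the observed (not
regression-predicted) last concentration; results carry the extrapolated
fraction and a warning flag above 20%. Censored observations enter AUC spans
as missing (bridged, not zeroed) and are excluded from the terminal
regression. CL and Vss are computed for plasma only; tissues report exposure
and half-life, with `Kp = AUC_tissue/AUC_plasma` as the partition summary.

## The pooled fit

Estimation is naive-pooled: one parameter vector per sex fit simultaneously
to the mean profiles of WT, KO and OT in all four matrices, with no weighting
by replicate count or SD (the SDs exist for the generator, not the
objective). The likelihood is proportional-error Gaussian with a single
variance `var_P` shared across groups and matrices, matching the single
reported variance per sex:

NLL = ½ Σ [ ln(2π·var_P·f²) + (obs − f)² / (var_P·f²) ].

Choices that make this fit behave:

* **Log-parameter space.** All estimated parameters are positive; the
  optimizer works on logs, and CV% is reported by the delta method from the
  log-scale observed information (CV% = 100 × log-scale SE), the convention
  the study's table uses.
* **var_P profiled out.** Given structural parameters, the conditional MLE
  of var_P is the mean squared proportional residual, so the outer
  optimization runs on the profiled likelihood. On noise-free data this lets
  the objective fall without bound as the fit approaches the truth, which is
  exactly the right behavior for recovery tests.
* **Stages.** A Levenberg–Marquardt stage on the proportional residual
  vector (whose sum of squares dominates the profiled NLL) does the heavy
  lifting; BFGS and Nelder–Mead then refine the exact profiled NLL. Plain
  gradient descent from distant starts diverges on this 16-parameter
  surface; LM does not. Multi-start (seeded log-normal jitter, default 5
  starts) guards against local minima.
* **Plausibility box.** Rates are kept in [1e-6, 1e4] /h and volumes in
  [0.1, 1e4] mL by a smooth quadratic penalty outside the box in log space
  (hard clamping creates flat plateaus that stall LM). Estimates ending on a
  limit are flagged; `kPgp_TRQ` in particular sits near its floor by design —
  the study's point is that tariquidar inhibition is essentially complete —
  and its CV% is marked unreliable there.
* **Non-rectangular designs.** Plasma is observed to 4 h, tissues to 2.5 h;
  the fitter simulates each group once at the union of its observation times
  and never assumes a rectangular design.

## What is, and is not, identifiable

With the study's sampling design and noise level, the systemic parameters
(V1, V1_TRQ, kel, kel_TRQ, k12, k21) are well identified: their
Hessian-based CVs (~7–20%) agree with a parametric bootstrap within a factor
of ~1.2, and Monte-Carlo refits recover them within a few percent. The CNS
exchange constants are a different story. The Fisher information at the
generating values puts their asymptotic CVs at 70–140%: the likelihood
surface has soft ridges along which k13/k31-type ratios are preserved while
the individual constants wander (refits reach objective values *below* the
truth's). Noise-free fits still pin `kPgp` to well under 1% from
twofold-perturbed starts — the ridge has a unique bottom — but under
realistic noise individual CNS rate constants should be read as order-of-
magnitude quantities, their ratios and the predicted concentration profiles
as the reliable outputs. `k15` and `k51` (CSF exchange with the central
compartment) and `kPgp_TRQ` (residual efflux with a ~5e-5 relative effect on
any prediction) are the weakest-identified parameters.

## The synthetic data generator

No raw animal data are deposited, so the generator is the stand-in, and its
defaults are the study conditions: serial plasma sampling at 5, 10, 15, 30,
45 min and 1, 1.5, 2, 2.5, 3, 4 h; destructive terminal sampling of plasma
and all CNS matrices at 0.16, 0.25, 0.5, 1, 1.5, 2, 2.5 h in independent
animal groups (5 per time point, the midpoint of the reported 4–6); 10 mg/kg
dosing; proportional Gaussian noise at the reported `var_P`, truncated at
zero by resampling (negligible bias at var_P ≈ 0.05); detection-limit
censoring at 0.010 µg/mL (plasma) and 0.050 µg/mL (CNS), applied per
replicate, with rows never dropped — a fully censored design point keeps its
row, flagged, with no mean. Terminal plasma samples pool with the sequential
arm unweighted at shared times. Seeds are mandatory; a dataset cannot be
produced without one, and regeneration under the same seed is byte-identical.

What it does not emulate: within-animal correlation in the sequential arm
(replicates are drawn independently — a documented simplification of the
crossover design), inter-animal kinetic variability (the source study fit mean
profiles; noise here is residual, not mixed-effects), assay bias, or
tariquidar's own concentrations. Passing recovery tests on these data
therefore says the estimator works under the stated error model, not that
the model is correct for real animals. One practical consequence of fitting
means of n replicates: the residual variance recovered from synthetic mean
profiles is ≈ var_P/n, not var_P.

## The inhibition scan

Forward simulations reduce `kPgp` to (1 − f) of its wild-type value with
everything else fixed, for f ∈ {0, 0.5, 0.9, 1} on a 0–2.5 h grid by
default. Ratios are always taken within a scan (same systemic parameter set,
WT by default; OT available), so systemic covariate effects cancel, and they
are dose-invariant because the model is linear. f = 1 reproduces the
knockout profiles exactly — a structural identity the tests assert. At 1 h
after the bolus, with the male parameters, 50% and 90% inhibition raise
brain concentration 1.58× and 2.87× and spinal cord concentration 1.43× and
2.19×. The corresponding in-text values in the source report (1.5/3 and
1.2/2) agree at integer precision for the 90% folds but not at one-decimal
precision for the 50% folds; no alternative reading of the simulation
(systemic set, sex, AUC or Cmax ratios, parameter-table digit splits)
reproduces all four printed values jointly, so the computed values stand.

## Numerical and degenerate-input conventions

Strictly increasing time grids; observation times at or after the dose time;
empty designs predict empty tables; zero dose simulates identically zero;
duplicate (group, sex, matrix, time) keys are rejected on read, as are
unknown group/sex/matrix labels (after case folding); minutes convert to
hours on read via an explicit units column or argument. Predictions are
floored at 1e-12 µg/mL inside the likelihood so a pathological parameter
vector produces a bad objective value instead of an exception; the same
floor guards fold-change baselines.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full study design (99 design
points per sex), 20 seeded Monte-Carlo refits for recovery, a 200-replicate
parametric bootstrap on the six systemic parameters, and 500 regenerations
for the noise-model check — sizes chosen so the whole suite exercises every
claim in a few minutes on a laptop while keeping the Monte-Carlo standard
errors comfortably inside the asserted tolerances.

## Known limitations

The CL implied by the compartmental estimates (kel·V1 ≈ 63 mL/h, male) is
~10× smaller than the published NCA clearance (525 mL/h); the discrepancy is
internal to the source report (a unit or normalization convention in the
original fit that it does not state) and is left unresolved — ratio-based
quantities are unaffected. Printed CV% values are not reproducible (the
original estimator is unspecified), and the asymptotic CVs computed here say
the printed ones understate the CNS parameters' uncertainty. Mean-profile
(naive-pooled) estimation cannot separate residual from inter-animal
variability; a mixed-effects treatment is out of scope.
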