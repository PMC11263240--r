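# cnspk

Semi-physiological pharmacokinetic analysis of ondansetron disposition into
the central nervous system of rats, and of what happens to that disposition
when P-glycoprotein (Pgp) efflux at the blood–brain barrier is removed —
genetically (Pgp-knockout animals) or pharmacologically (co-administration of
the Pgp inhibitor tariquidar).

Ondansetron, a 5-HT3 receptor antagonist of interest for neuropathic pain, is
a Pgp substrate: active efflux at the blood–brain barrier limits its exposure
at spinal and supraspinal targets. The package is written for
pharmacometricians and DMPK scientists who want to reproduce, probe or extend
the compartmental analysis of that system: the model and fitter, the
noncompartmental analysis (NCA), the inhibition simulations, and a
study-design-faithful synthetic data generator (the published study deposited
no raw data) are all first-class, tested code.

## The model

Amounts (µg) in five compartments — central (A1, volume V1), peripheral
(A2), brain (A3, 1.8 mL), spinal cord (A4, 0.6 mL) and CSF (A5, 0.25 mL) —
follow a linear system after an IV bolus into A1:

    dA1/dt = k21·A2 + k31·A3 + k41·A4 + k51·A5
             − (kel + k12 + k13 + k14 + k15)·A1 + kPgp·A3 + kPgp·A4
    dA2/dt = k12·A1 − k21·A2
    dA3/dt = k13·A1 + k53·A5 − (k31 + k35 + kPgp)·A3
    dA4/dt = k14·A1 + k54·A5 − (k41 + k45 + kPgp)·A4
    dA5/dt = k15·A1 + k35·A3 + k45·A4 − (k51 + k53 + k54)·A5

with one first-order Pgp efflux constant kPgp acting identically on brain and
spinal cord. Study groups map onto the shared parameter vector: wild type
(WT) uses it unchanged; knockout (KO) sets kPgp = 0; the
ondansetron+tariquidar group (OT) swaps in covariate values V1_TRQ, kel_TRQ
and a residual efflux kPgp_TRQ (tariquidar is a categorical covariate, not a
modeled species). Estimation is naive-pooled maximum likelihood on mean
profiles of all groups and matrices simultaneously (per sex) under a
proportional error model with a single variance var_P; NCA reports AUC,
λz/t½, MRT, CL, Vss and the tissue partition coefficients
Kp = AUC_tissue/AUC_plasma.

## Worked example

Simulate the male wild-type model, ask what 50% and 90% Pgp inhibition do to
brain exposure one hour after a 10 mg/kg bolus, and run NCA on a synthetic
replicate of the study:

```r
library(cnspk)

params <- default_parameters("male")$params          # packaged estimates
dose   <- dose_from_weight(10, default_body_weight("M"))  # 3250 ug

sc <- scan_spec(params, systemic = "WT", dose = dose)
fold_change(sc, "brain", time = 1, fraction = 0.5)$ratio
#> [1] 1.577036
fold_change(sc, "brain", time = 1, fraction = 0.9)$ratio
#> [1] 2.868055

ds  <- generate_dataset(params, study_design(sexes = "M"),
                        var_p = 0.05, seed = 20240)
res <- nca_dataset(ds, dose_map = c(M = dose$amount))
subset(res, matrix == "brain", c(group, auc_inf, t_half, kp))
#>   group   auc_inf    t_half       kp
#> 2    WT  54.89712 0.4829380 1.319594
#> 6    KO 173.02721 0.5275439 4.011259
#> 10   OT 190.59015 0.6146869 2.996591
```

Halving the efflux rate raises brain concentration 1.6-fold at 1 h; a 90%
block raises it ~3-fold. In the synthetic NCA, losing Pgp (KO) or inhibiting
it (OT) lifts the brain partition coefficient from ~1.3 to 3–4, mirroring
the direction and magnitude of the study's contrast.

The numbered drivers under `analysis/` run the full workflow
(`01_simulate_profiles.R` … `05_inhibition_scan.R`), writing tables under
`results/analysis/`; `run_pipeline()` orchestrates the same stages from a
config list or YAML file.

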