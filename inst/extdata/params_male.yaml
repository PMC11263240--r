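# Final-model parameter estimates, male pooled fit (WT-M, KO-M, OT-M).
# Units: volumes mL, rate constants 1/h. Volumes are fixed, never estimated.
# NOTE: the printed source runs estimate and CV% digits together for a few
# rows; the splits adopted for k_15 (0.081 | 29), k_51 (6.84 | 64),
# k_Pgp,TRQ (0.0021 | 10) and var_P (0.05 | 18) are provisional.
sex: M
parameters:
  V_1: {estimate: 17.5, cv_percent: 6}
  "V_1,TRQ": {estimate: 12.7, cv_percent: 6}
  k_el: {estimate: 3.60, cv_percent: 9}
  "k_el,TRQ": {estimate: 3.38, cv_percent: 9}
  k_12: {estimate: 2.14, cv_percent: 22}
  k_21: {estimate: 2.62, cv_percent: 9}
  k_13: {estimate: 17.6, cv_percent: 16}
  k_31: {estimate: 39.6, cv_percent: 16}
  k_14: {estimate: 9.37, cv_percent: 18}
  k_41: {estimate: 71.0, cv_percent: 18}
  k_15: {estimate: 0.081, cv_percent: 29}
  k_51: {estimate: 6.84, cv_percent: 64}
  "k_35=45": {estimate: 0.928, cv_percent: 21}
  "k_53=54": {estimate: 66.6, cv_percent: 16}
  k_Pgp: {estimate: 81.9, cv_percent: 16}
  "k_Pgp,TRQ": {estimate: 0.0021, cv_percent: 10}
  V_brain: {estimate: 1.8, fixed: true}
  V_spinal: {estimate: 0.6, fixed: true}
  V_CSF: {estimate: 0.25, fixed: true}
  var_P: {estimate: 0.05, cv_percent: 18}
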