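# Final-model parameter estimates, female pooled fit (WT-F, KO-F, OT-F).
# Units: volumes mL, rate constants 1/h. Volumes are fixed, never estimated.
# The digit splits flagged in params_male.yaml apply here analogously
# (var_P 0.03 | 19, k_Pgp,TRQ 0.00015 | 9).
sex: F
parameters:
  V_1: {estimate: 13.3, cv_percent: 7}
  "V_1,TRQ": {estimate: 11.3, cv_percent: 7}
  k_el: {estimate: 5.06, cv_percent: 11}
  "k_el,TRQ": {estimate: 3.02, cv_percent: 11}
  k_12: {estimate: 4.37, cv_percent: 19}
  k_21: {estimate: 2.32, cv_percent: 10}
  k_13: {estimate: 13.0, cv_percent: 14}
  k_31: {estimate: 25.2, cv_percent: 18}
  k_14: {estimate: 3.60, cv_percent: 17}
  k_41: {estimate: 31.5, cv_percent: 22}
  k_15: {estimate: 0.518, cv_percent: 17}
  k_51: {estimate: 47.3, cv_percent: 25}
  "k_35=45": {estimate: 0.914, cv_percent: 18}
  "k_53=54": {estimate: 79.9, cv_percent: 15}
  k_Pgp: {estimate: 101, cv_percent: 19}
  "k_Pgp,TRQ": {estimate: 0.00015, cv_percent: 9}
  V_brain: {estimate: 1.8, fixed: true}
  V_spinal: {estimate: 0.6, fixed: true}
  V_CSF: {estimate: 0.25, fixed: true}
  var_P: {estimate: 0.03, cv_percent: 19}
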