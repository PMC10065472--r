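# Comparative-risk-assessment parameters (editable configuration).
#
# These are illustrative defaults at literature-style magnitudes, shipped so
# the model runs out of the box; substitute meta-analytic estimates for any
# production analysis. Units:
#   energy_to_weight : kg steady-state body-weight change per kcal/day change
#   sodium_to_sbp    : mmHg systolic blood pressure per g salt per day
#   satfat_to_chol   : mmol/L total cholesterol per %TE saturated fat
#   sodium_salt_factor: g salt per g sodium
#   rr_per_unit      : log-linear relative risk per mediator unit
#   se_log           : SE of log(rr) (lognormal Monte Carlo sampling)
mediators:
  energy_to_weight:
    value: 0.042        # ~ 1 kcal/day sustained ~ 0.042 kg steady-state
    se: 0.008
  sodium_to_sbp:
    value: 2.0          # mmHg per g salt/day, population average
    se: 0.4
  satfat_to_chol:
    value: 0.052        # mmol/L per %TE substitution
    se: 0.010
  sodium_salt_factor: 2.5
relative_risks:
  - disease: CVD
    mediator: sbp
    rr_per_unit: 1.025
    se_log: 0.004
  - disease: CVD
    mediator: chol
    rr_per_unit: 1.20
    se_log: 0.030
  - disease: CVD
    mediator: bmi
    rr_per_unit: 1.05
    se_log: 0.010
  - disease: diabetes
    mediator: bmi
    rr_per_unit: 1.15
    se_log: 0.020
  - disease: cancer
    mediator: bmi
    rr_per_unit: 1.03
    se_log: 0.008
  - disease: chronic renal failure
    mediator: sbp
    rr_per_unit: 1.02
    se_log: 0.005
  - disease: chronic renal failure
    mediator: bmi
    rr_per_unit: 1.06
    se_log: 0.015
  - disease: liver disease
    mediator: bmi
    rr_per_unit: 1.08
    se_log: 0.020
exposure_forms:
  energy: lognormal
  sodium: lognormal
  satfat_pcte: normal
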