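# Default analysis configuration: serplulimab + chemotherapy (cisplatin /
# 5-FU) vs chemotherapy alone, first line, PD-L1-positive advanced ESCC.
# Costs are USD per monthly cycle (converted at $1 = 6.77 yuan, BSA 1.72 m2,
# weight 65 kg dosing); Weibull parameters are the published fits per
# PD-L1 CPS stratum. The cps_ge10 comparator OS parameters are reproduced
# as published even though they are inconsistent with the trial's reported
# subgroup medians (documented erratum); full-model results for that
# stratum should be interpreted accordingly.
settings:
  cycle_length: 1            # months
  horizon_cycles: 120        # 10 years
  discount_rate_annual: 0.05
  wtp_per_qaly: 37663.26     # 3x per-capita GDP, USD/QALY
  half_cycle_correction: true
utilities:
  pfs: 0.68
  pd: 0.42
populations:
  cps_ge1:
    intervention:
      name: serplulimab_chemotherapy
      costs:
        drug: 3415.47
        chemotherapy: 705.15
        antiemetics: 200.16
        tests: 384.63
        adverse_events: 50.13
        hospitalization: 40.34
        subsequent_therapy: 430.95
      pfs: {scale_lambda: 0.0594, shape_gamma: 1.275}
      os:  {scale_lambda: 0.0119, shape_gamma: 1.478}
    comparator:
      name: chemotherapy
      costs:
        chemotherapy: 578.75
        antiemetics: 164.28
        tests: 330.37
        adverse_events: 40.86
        hospitalization: 33.11
        subsequent_therapy: 869.24
      pfs: {scale_lambda: 0.0595, shape_gamma: 1.532}
      os:  {scale_lambda: 0.0158, shape_gamma: 1.482}
  cps_1to10:
    intervention:
      name: serplulimab_chemotherapy
      costs:
        drug: 3415.47
        chemotherapy: 705.15
        antiemetics: 200.16
        tests: 384.63
        adverse_events: 50.13
        hospitalization: 40.34
        subsequent_therapy: 430.95
      pfs: {scale_lambda: 0.0678, shape_gamma: 1.258}
      os:  {scale_lambda: 0.0176, shape_gamma: 1.396}
    comparator:
      name: chemotherapy
      costs:
        chemotherapy: 578.75
        antiemetics: 164.28
        tests: 330.37
        adverse_events: 40.86
        hospitalization: 33.11
        subsequent_therapy: 869.24
      pfs: {scale_lambda: 0.0655, shape_gamma: 1.513}
      os:  {scale_lambda: 0.0125, shape_gamma: 1.667}
  cps_ge10:
    intervention:
      name: serplulimab_chemotherapy
      costs:
        drug: 3415.47
        chemotherapy: 705.15
        antiemetics: 200.16
        tests: 384.63
        adverse_events: 50.13
        hospitalization: 40.34
        subsequent_therapy: 430.95
      pfs: {scale_lambda: 0.0456, shape_gamma: 1.294}
      os:  {scale_lambda: 0.0086, shape_gamma: 1.504}
    comparator:
      name: chemotherapy
      costs:
        chemotherapy: 578.75
        antiemetics: 164.28
        tests: 330.37
        adverse_events: 40.86
        hospitalization: 33.11
        subsequent_therapy: 869.24
      pfs: {scale_lambda: 0.0228, shape_gamma: 1.354}
      os:  {scale_lambda: 0.0536, shape_gamma: 1.619}
owsa:
  span: 0.20
psa:
  iterations: 1000
  se_fraction: 0.20
  wtp_grid: {from: 0, to: 250000, by: 2500}
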