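# Published base-case results (EUR 2020): per-patient 5-year discounted costs
# by category with percentage shares, life-years and QALYs, increments
# (arm A minus arm B), the ICUR, and headline sensitivity-analysis figures.
cost_eur:
  A: {diagnosis: 191.60, medication: 341.28, addon_followup: 1337.59, osd_management: 477.27, overall: 2347.74}
  B: {diagnosis: 192.75, medication: 241.81, addon_followup: 1339.40, osd_management: 566.38, overall: 2340.34}
  difference: {diagnosis: -1.15, medication: 99.47, addon_followup: -1.81, osd_management: -89.11, overall: 7.39}
shares_pct:
  A: {diagnosis: 8.16, medication: 14.54, addon_followup: 56.97, osd_management: 20.33}
  B: {diagnosis: 8.24, medication: 10.33, addon_followup: 57.23, osd_management: 24.20}
lys: {A: 4.228, B: 4.223, difference: 0.005, diff_lo: -0.013, diff_hi: 0.023}
qalys: {A: 2.539, B: 2.191, difference: 0.348, diff_lo: 0.285, diff_hi: 0.408}
delta_cost_ci: {lo: -159.39, hi: 166.60}
icur_eur_per_qaly: 21.26
wtp_range_eur: [30000, 50000]
trace_per_1000:
  stage0: {A: 672, A_sd: 215, B: 649, B_sd: 228}
  stage5: {A: 5, A_sd: 7, B: 6, B_sd: 8}
  deaths: {A: 114, A_sd: 81, B: 115, B_sd: 82}
owsa:
  max_icur: 235
  tonometry_stage0_pct: [-786.85, 889.91]
  visual_field_stage0_pct: [-691.95, 785.46]
psa:
  iterations: 10000
  cep: {NE: 5088, SE: 4912}
  p_ce_at_30000: 1.0000
  ceaf_switch_threshold: 200.20
  p_optimal_at_switch: 0.7901
  p_optimal_from_1000: 1.0000
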