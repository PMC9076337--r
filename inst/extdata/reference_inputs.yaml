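# Published base-case model inputs (EUR 2020): drug per-diems, outpatient
# procedure tariffs with 95% CIs where printed, stage utilities per arm and
# the ocular-surface-disease disutility and annual probabilities.
# Drug per-diems carry no CI (exogenous prices).
drug_per_diem_eur:
  STN1013001: 0.30
  latanoprost: 0.24
  acetazolamide: 0.16
  brimonidine: 0.12
  brinzolamide: 0.12
  brinzolamide_brimonidine: 0.28
  dorzolamide: 0.14
  timolol: 0.18
  timolol_dorzolamide: 0.20
  cyclosporin: 3.67
  preservative_free_lubricant: 0.27
pack_duration_days:
  STN1013001: 30.0
  latanoprost: 29.73
  addon_mean: 29.0
  osd_drug_mean: 30.0
therapy_days_per_year: 365.25
procedure_tariff_eur:
  breakup_time_test: {cost: 19.20, lo: 15.44, hi: 22.96}
  diurnal_iop_curve: {cost: 41.66, lo: 33.49, hi: 49.83}
  fluorescein_test: {cost: 19.20, lo: 15.44, hi: 22.96}
  gonioscopy: {cost: 17.28, lo: 13.89, hi: 20.67}
  lissamine_test: {cost: 19.20, lo: 15.44, hi: 22.96}
  oct_rnfl: {cost: 56.54, lo: 45.46, hi: 67.62}
  retinal_fiber_thickness: {cost: 26.78, lo: 21.53, hi: 32.03}
  schirmer_test: {cost: 19.20, lo: 15.44, hi: 22.96}
  slit_lamp: {cost: 28.29, lo: 24.92, hi: 37.06}
  tonometry: {cost: 41.66, lo: 11.21, hi: 16.67}
  visual_field_test: {cost: 39.43, lo: 31.70, hi: 47.16}
  ophthalmologist_visit: {cost: 25.32, lo: 20.36, hi: 30.28}
utility:
  A:
    stage0: {u: 0.900, lo: 0.885, hi: 0.915}
    stage1: {u: 0.897, lo: 0.880, hi: 0.913}
    stage2: {u: 0.879, lo: 0.860, hi: 0.896}
    stage3: {u: 0.862, lo: 0.840, hi: 0.883}
    stage4: {u: 0.825, lo: 0.795, hi: 0.853}
    stage5: {u: 0.790, lo: 0.750, hi: 0.828}
  B:
    stage0: {u: 0.900, lo: 0.884, hi: 0.915}
    stage1: {u: 0.890, lo: 0.872, hi: 0.908}
    stage2: {u: 0.866, lo: 0.845, hi: 0.885}
    stage3: {u: 0.849, lo: 0.825, hi: 0.871}
    stage4: {u: 0.808, lo: 0.776, hi: 0.838}
    stage5: {u: 0.790, lo: 0.748, hi: 0.829}
osd_disutility: {d: -0.120, lo: -0.231, hi: -0.045}
osd_prob: {A: 0.762, B: 0.837}
econ:
  discount_rate: 0.025
  owsa_discount_rate: [0.0, 0.045]
  horizon_cycles: 5
  cycle_length_days: 365.25
  cohort_size: 1000
  entry_age_years: 47.31
  female_fraction: 0.50
  currency_year: EUR2020
  wtp_range_eur_per_qaly: [30000, 50000]
diagnosis_volumes:
  slit_lamp: {A: 1.18, A_lo: 0.83, A_hi: 1.59, B: 1.19, B_lo: 0.97, B_hi: 1.43}
  tonometry: {A: 1.18, A_lo: 0.83, A_hi: 1.59, B: 1.19, B_lo: 0.97, B_hi: 1.43}
  ophthalmologist_visit: {A: 1.24, A_lo: 1.02, A_hi: 1.49, B: 1.26, B_lo: 1.05, B_hi: 1.49}
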