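params:
  os_scale: 0.004716
  os_shape: 1.533854
  pfs_scale: 0.003867
  pfs_shape: 2.335407
  hr_os: 0.654
  hr_pfs: 0.405
  p_disc_combo: 0.004298
  p_disc_chemo: 0.006372
  price_ly01008: 24.99
  price_paclitaxel: 57.51
  price_carboplatin: 1.37
  price_nivolumab: 60.35
  cost_followup: 55.6
  cost_subsequent: 854.05
  cost_bsc: 337.5
  cost_palliative: 2627.8
  cost_ae_combo: 1025.82
  cost_ae_chemo: 745.01
  u_pfs: 0.856
  u_pd: 0.768
  du_combo: 0.061
  du_chemo: 0.08
  discount_rate: 0.05
  weight: 65.0
  bsa: 1.72
  crcl: 70.0
cycle_days: 21
horizon_years: 30.0
wtp_per_qaly: 33438.0
fx_cny_per_usd: 6.8974
max_chemo_cycles: 5
carboplatin_auc: 5.0
p_subsequent_therapy: 0.6425
ly01008_mg_per_kg: 15.0
billing: linear
half_cycle_correction: no
hr_psa_dist: normal
calibration:
  max_chemo_cycles: 5
  carboplatin_auc: 5.0
  p_subsequent_therapy: 0.6425
  billing: linear
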