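natural_history:
  p_normal_to_low: 0.016
  p_low_to_high: 0.02
  p_high_to_crc: 0.05
  p_stage_progress:
    I: 0.3
    II: 0.35
    III: 0.45
  p_symptomatic:
    I: 0.03
    II: 0.08
    III: 0.18
    IV: 0.45
  m_crc:
    I: 0.01
    II: 0.05
    III: 0.14
    IV: 0.45
  crc_entry_stage_dist:
    I: 1.0
    II: 0.0
    III: 0.0
    IV: 0.0
  initial_distribution:
    NORMAL: 0.85
    LOW_RISK_POLYP: 0.12
    HIGH_RISK_POLYP: 0.03
mortality:
- sex: male
  age_band_start: 50
  age_band_end: 54
  all_cause_rate: 0.0044
  crc_rate: 0.00025
- sex: male
  age_band_start: 55
  age_band_end: 59
  all_cause_rate: 0.0066
  crc_rate: 0.0004
- sex: male
  age_band_start: 60
  age_band_end: 64
  all_cause_rate: 0.0106
  crc_rate: 0.0006
- sex: male
  age_band_start: 65
  age_band_end: 69
  all_cause_rate: 0.0176
  crc_rate: 0.00085
- sex: male
  age_band_start: 70
  age_band_end: 74
  all_cause_rate: 0.0287
  crc_rate: 0.0011
- sex: male
  age_band_start: 75
  age_band_end: 99
  all_cause_rate: 0.056
  crc_rate: 0.0015
- sex: female
  age_band_start: 50
  age_band_end: 54
  all_cause_rate: 0.0025
  crc_rate: 0.00015
- sex: female
  age_band_start: 55
  age_band_end: 59
  all_cause_rate: 0.0038
  crc_rate: 0.00025
- sex: female
  age_band_start: 60
  age_band_end: 64
  all_cause_rate: 0.006
  crc_rate: 0.0004
- sex: female
  age_band_start: 65
  age_band_end: 69
  all_cause_rate: 0.0102
  crc_rate: 0.00055
- sex: female
  age_band_start: 70
  age_band_end: 74
  all_cause_rate: 0.0175
  crc_rate: 0.00075
- sex: female
  age_band_start: 75
  age_band_end: 99
  all_cause_rate: 0.04
  crc_rate: 0.001
tests:
  gfobt:
    sens_low_polyp: 0.08
    sens_high_polyp: 0.2
    sens_crc:
      I: 0.7
      II: 0.7
      III: 0.7
      IV: 0.7
    specificity: 0.925
    p_bleed: 0.0
    p_perforation: 0.0
    m_bleed: 0.0
    m_perforation: 0.0
  ifobt:
    sens_low_polyp: 0.12
    sens_high_polyp: 0.3
    sens_crc:
      I: 0.82
      II: 0.82
      III: 0.82
      IV: 0.82
    specificity: 0.95
    p_bleed: 0.0
    p_perforation: 0.0
    m_bleed: 0.0
    m_perforation: 0.0
  colonoscopy:
    sens_low_polyp: 1.0
    sens_high_polyp: 1.0
    sens_crc:
      I: 1.0
      II: 1.0
      III: 1.0
      IV: 1.0
    specificity: 1.0
    p_bleed: 0.0025
    p_perforation: 0.001
    m_bleed: 0.01
    m_perforation: 0.05
compliance:
  c_screen: 0.6
  c_followup: 0.8
  c_symptomatic: 1.0
costs:
  unit_cost:
    gfobt: 5.0
    ifobt: 13.0
    colonoscopy: 640.0
    polypectomy: 160.0
    complication_bleed: 1500.0
    complication_perforation: 5000.0
    specialist_visit: 90.0
  initial_cost:
    I: 15000.0
    II: 22000.0
    III: 30000.0
    IV: 38000.0
  continuing_cost:
    I: 800.0
    II: 1200.0
    III: 2500.0
    IV: 12000.0
  hkd_per_usd: 7.8
utilities:
  u:
    NORMAL: 1.0
    LOW_RISK_POLYP: 0.99
    HIGH_RISK_POLYP: 0.98
    UNDIAG_CRC_I: 0.83
    UNDIAG_CRC_II: 0.8
    UNDIAG_CRC_III: 0.73
    UNDIAG_CRC_IV: 0.63
    DIAG_CRC_I: 0.83
    DIAG_CRC_II: 0.8
    DIAG_CRC_III: 0.73
    DIAG_CRC_IV: 0.63
  sets:
    ramsey:
      cancer_free: 1.0
      I: 0.9
      II: 0.9
      III: 0.8
      IV: 0.76
    ness:
      cancer_free: 0.91
      I: 0.74
      II: 0.7
      III: 0.5
      IV: 0.25
    sharp:
      cancer_free: 0.94
      I: 0.8
      II: 0.8
      III: 0.8
      IV: 0.8
econ:
  discount_rate: 0.035
  horizon_years: 25
  cycle_length: 1
  cohort_size: 100000
  entry_age: 50
  exit_age: 75
  wtp_threshold: 50000.0
  half_cycle_correction: yes
  sex_weights:
    male: 0.5
    female: 0.5
meta:
  label: fixture-hk2009
  source_tags:
    paper:
    - compliance
    - costs.hkd_per_usd
    - utilities.sets
    - utilities.u.NORMAL
    - econ
    placeholder:
    - natural_history
    - mortality
    - tests
    - costs.unit_cost
    - costs.initial_cost
    - costs.continuing_cost
    - utilities.u (non-normal states)
strategies:
- name: No screening
  test: none
- name: Annual G-FOBT
  test: gfobt
  interval_years: 1
- name: Biennial G-FOBT
  test: gfobt
  interval_years: 2
- name: Annual I-FOBT
  test: ifobt
  interval_years: 1
- name: Biennial I-FOBT
  test: ifobt
  interval_years: 2
- name: Colonoscopy every 10 years
  test: colonoscopy
  interval_years: 10
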