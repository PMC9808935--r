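# Base-case model configuration: TAVI vs SAVR, healthcare-payer
# perspective, costs in 2020 Iranian Rial. Identical to default_config().
utilities:
  mean: {NYHA1: 0.72, NYHA2: 0.72, NYHA3: 0.53, NYHA4: 0.47}
  sd:   {NYHA1: 0.25, NYHA2: 0.25, NYHA3: 0.32, NYHA4: 0.35}
  stroke_disutility: 0.39

events:
  # trial-horizon cumulative probabilities (five-year follow-up)
  followup_years: 5
  TAVI:
    TIA: 0.053
    stroke: 0.153
    rehospitalization: 0.333
    myocardial_infarction: 0.111
    new_atrial_fibrillation: 0.158
    new_pacemaker: 0.155
    aortic_valve_reintervention: 0.032
  SAVR:
    TIA: 0.043
    stroke: 0.125
    rehospitalization: 0.252
    myocardial_infarction: 0.082
    new_atrial_fibrillation: 0.304
    new_pacemaker: 0.130
    aortic_valve_reintervention: 0.008

entry:
  # 0-12-month outcome distribution; each arm sums to 1
  TAVI: {NYHA1: 0.36, NYHA2: 0.28, NYHA3: 0.10, NYHA4: 0.01, death: 0.25}
  SAVR: {NYHA1: 0.34, NYHA2: 0.30, NYHA3: 0.07, NYHA4: 0.02, death: 0.27}

costs:
  - name: savr_procedure
    mean: 12811000
    sampling: FIXED
    assignment:
      - {arm: SAVR, phase: PROCEDURE}
  - name: tavi_procedure
    mean: 20052000
    sampling: FIXED
    assignment:
      - {arm: TAVI, phase: PROCEDURE}
  - name: tavi_hospitalization
    mean: 43200000
    sd: 4032654
    sampling: GAMMA
    assignment:
      - {arm: TAVI, phase: PROCEDURE}
      - {arm: TAVI, phase: PER_CYCLE_EVENT, event: rehospitalization}
  - name: savr_hospitalization
    mean: 75750000
    sd: 4326731
    sampling: GAMMA
    assignment:
      - {arm: SAVR, phase: PROCEDURE}
      - {arm: SAVR, phase: PER_CYCLE_EVENT, event: rehospitalization}
  - name: tavi_stent
    mean: 450000000
    sampling: FIXED
    assignment:
      - {arm: TAVI, phase: PROCEDURE}
  - name: valve_prosthesis
    mean: 800000000
    sampling: FIXED
    assignment:
      - {arm: TAVI, phase: ACUTE_EVENT, event: aortic_valve_reintervention}
      - {arm: SAVR, phase: ACUTE_EVENT, event: aortic_valve_reintervention}
  - name: pacemaker_icd
    mean: 9183500
    sampling: FIXED
    assignment:
      - {arm: TAVI, phase: ACUTE_EVENT, event: new_pacemaker}
      - {arm: SAVR, phase: ACUTE_EVENT, event: new_pacemaker}
  - name: angioplasty
    mean: 7398300
    sampling: FIXED
    assignment:
      - {arm: TAVI, phase: ACUTE_EVENT, event: myocardial_infarction}
      - {arm: SAVR, phase: ACUTE_EVENT, event: myocardial_infarction}
  - name: tavi_reoperation
    mean: 10026000
    sd: 1430401
    sampling: GAMMA
    assignment:
      - {arm: TAVI, phase: ACUTE_EVENT, event: aortic_valve_reintervention}
  - name: savr_reoperation
    mean: 6405500
    sd: 2720528
    sampling: GAMMA
    assignment:
      - {arm: SAVR, phase: ACUTE_EVENT, event: aortic_valve_reintervention}
  - name: cabg
    mean: 22280000
    sampling: FIXED
    assignment:
      - {arm: TAVI, phase: ACUTE_EVENT, event: myocardial_infarction}
      - {arm: SAVR, phase: ACUTE_EVENT, event: myocardial_infarction}

econ:
  discount_rate: 0.065
  exchange_rate: 250000
  # quarter-GDP-per-capita steps from 0 to 4x; includes the 1x and 3x
  # GDP anchors (551,400,000 and 1,654,200,000 IRR per QALY) exactly
  wtp_grid: [0, 137850000, 275700000, 413550000, 551400000, 689250000,
             827100000, 964950000, 1102800000, 1240650000, 1378500000,
             1516350000, 1654200000, 1792050000, 1929900000, 2067750000,
             2205600000]
  cycle_length_years: 1
  max_cycles: 50
  survival_stop_epsilon: 0.0001
  half_cycle_correction: false

knobs:
  longterm_death_mode: CONSTANT_YEAR1
  event_annualization: CUMULATIVE_OVER_FOLLOWUP
  rehospitalization_recurring: true
  owsa_mode: MULTIPLIER
  owsa_grid: [0.05, 0.25, 0.50, 0.75, 1.00, 1.50, 2.00, 2.50]
  psa_icer_summary: RATIO_OF_MEANS
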