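# end-to-end demo: synthetic 2,000-patient cohort with a planted risk rule
seed: 42
synthetic:
  n_patients: 2000
  n_diseases: 50
  n_modules: 4
  baseline_prevalence: 0.02
  within_module_boost: 8
  n_visits_range: [2, 5]
  risk_rule:
    target_disease: D011
    risk_diseases: [A001, B001, C001]
    trigger_probability: 0.8
    background_probability: 0.05
thresholds:
  min_cooccurrence: 5
  min_rr: 1.0
  min_phi: 0.0
validation:
  n_genes: 1000
  n_pathways: 50
  coupling: 0.8
prediction:
  target: D011
  n_neg: 500
  n_pos: 500
  folds: 5
  models: [lr, rf]
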