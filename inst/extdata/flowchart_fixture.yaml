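mode: fixture
counts:
  eligible_untreated: 1344
  eligible_treated: 464
  no_followup: 385
  prior_malignancy: 557
  prior_fracture: 1769
  prior_aom: 179
  under_50: 0
  paget_history: 0
  outside_window: 0
observation:
  start: '2010-01-01'
  end: '2014-12-31'
seed: 20100101
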