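mode: population
n_patients: 2000
incidence: 0.05
p_treat: 0.21
p_fu: 0.82
seed: 7
observation:
  start: '2010-01-01'
  end: '2014-12-31'
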