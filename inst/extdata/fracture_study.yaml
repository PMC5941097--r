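version: 1
studies:
- topic: incident_osteoporotic_fracture
  observation:
    start: '2010-01-01'
    end: '2014-12-31'
  index:
    template: osteoporotic_fracture
    settings:
    - outpatient
    - admission
    - emergency
    first_ever: no
  criteria:
  - label: age 50 or over at index
    action: require_presence
    age_minimum: 50
  - label: no malignant neoplasm in prior year
    action: exclude_if_present
    template: malignancy
    window:
    - -365
    - -1
  - label: no osteoporotic fracture in prior year
    action: exclude_if_present
    template: osteoporotic_fracture
    window:
    - -365
    - -1
  - label: no Paget disease in prior year
    action: exclude_if_present
    template: paget
    window:
    - -365
    - -1
  - label: no AOM dispensing in prior year
    action: exclude_if_present
    template: aom
    window:
    - -365
    - -1
- topic: continued_followup
  source_list: incident_osteoporotic_fracture
  observation:
    start: '2010-01-01'
    end: '2014-12-31'
  index:
    template: osteoporotic_fracture
    settings:
    - outpatient
    - admission
    - emergency
    first_ever: no
  criteria:
  - label: encounter within 90 days post index
    action: require_presence
    encounter: yes
    window:
    - 1
    - 90
- topic: aom_treated
  source_list: incident_osteoporotic_fracture
  observation:
    start: '2010-01-01'
    end: '2014-12-31'
  index:
    template: osteoporotic_fracture
    settings:
    - outpatient
    - admission
    - emergency
    first_ever: no
  criteria:
  - label: AOM dispensing within 1 year post index
    action: require_presence
    template: aom
    window:
    - 1
    - 365
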