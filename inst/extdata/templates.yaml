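version: 1
templates:
- name: hip_fracture
  dimension: diagnosis
  description: Hip fracture (ICD-9 820)
  public: yes
  patterns:
  - kind: prefix
    value: '820'
- name: vertebral_fracture
  dimension: diagnosis
  description: Vertebral fracture (ICD-9 805, 806)
  public: yes
  patterns:
  - kind: prefix
    value: '805'
  - kind: prefix
    value: '806'
- name: osteoporotic_fracture
  dimension: diagnosis
  description: Hip or vertebral fracture (ICD-9 820, 805, 806)
  public: yes
  patterns:
  - kind: prefix
    value: '820'
  - kind: prefix
    value: '805'
  - kind: prefix
    value: '806'
- name: malignancy
  dimension: diagnosis
  description: Malignant neoplasm (ICD-9 140-208)
  public: yes
  patterns:
  - kind: range
    low: 140
    high: 208
- name: paget
  dimension: diagnosis
  description: Paget disease of bone (ICD-9 731.0)
  public: yes
  patterns:
  - kind: exact
    value: '731.0'
- name: aom
  dimension: pharmacy
  description: Anti-osteoporosis medications (9 drugs)
  public: yes
  patterns:
  - kind: exact
    value: alendronate
  - kind: exact
    value: zolendronate
  - kind: exact
    value: ibandronate
  - kind: exact
    value: denosumab
  - kind: exact
    value: raloxifene
  - kind: exact
    value: teriparatide
  - kind: exact
    value: estradiol valerate
  - kind: exact
    value: conjugated estrogens
  - kind: exact
    value: calcitonin
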