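vitals:
- vital: sbp
  standard: 140.0
  severe: 160.0
  direction: ge
- vital: hr
  standard: 110.0
  severe: 120.0
  direction: ge
- vital: rr
  standard: 24.0
  severe: 30.0
  direction: ge
- vital: spo2
  standard: 96.0
  severe: 94.0
  direction: le
severe_symptoms:
- dyspnea
- orthopnea
age_threshold: 35.0
count_for_red_flag: 4
static_in_count: yes
dedupe_tachypnea: no
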