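# Condition -> code-prefix map (implementer-supplied ICD-10-CM conventions;
# the study did not publish its code lists). Matching is case- and
# dot-insensitive prefix matching. Edit freely and load with read_code_map().
diagnosis:
  preeclampsia:
  - O140
  - O141
  - O149
  eclampsia: O15
  cardiomyopathy:
  - O903
  - I42
  myocardial_infarction: I21
  heart_failure: I50
  acute_kidney_disease_failure: N17
  cerebral_infarction: I63
  pulmonary_embolism: I26
  venous_thromboembolism:
  - I82
  - O223
  hellp: O142
intervention:
  preeclampsia: RX_PREECLAMPSIA
  eclampsia: RX_ECLAMPSIA
  cardiomyopathy: RX_CARDIOMYOPATHY
  myocardial_infarction: RX_MYOCARDIAL_INFARCTION
  heart_failure: RX_HEART_FAILURE
  acute_kidney_disease_failure: RX_ACUTE_KIDNEY_DISEASE_FAILURE
  cerebral_infarction: RX_CEREBRAL_INFARCTION
  pulmonary_embolism: RX_PULMONARY_EMBOLISM
  venous_thromboembolism: RX_VENOUS_THROMBOEMBOLISM
  hellp: RX_HELLP
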