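attributes:
- name: place
  levels:
  - gp_surgery
  - home_visit
  - outpatient_clinic
  reference: gp_surgery
  coding: dummy
- name: review
  levels:
  - non_medicinal_only
  - comprehensive
  reference: non_medicinal_only
  coding: dummy
- name: support
  levels:
  - none
  - social_worker_only
  - therapists_and_social_worker
  reference: none
  coding: dummy
- name: waiting
  levels:
  - 2_weeks
  - 4_weeks
  - 8_weeks
  reference: 8_weeks
  coding: dummy
  values:
    2_weeks: 2.0
    4_weeks: 4.0
    8_weeks: 8.0
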