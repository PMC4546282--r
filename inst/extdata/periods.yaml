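- name: Lithic
  start_ybp: 15000.0
  end_ybp: 2500.0
- name: Preclassic
  start_ybp: 2500.0
  end_ybp: 1750.0
- name: Classic
  start_ybp: 1750.0
  end_ybp: 1050.0
- name: Postclassic
  start_ybp: 1050.0
  end_ybp: 429.0
- name: Colonial
  start_ybp: 429.0
  end_ybp: 0.0
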