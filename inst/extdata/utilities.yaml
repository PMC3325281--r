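# Health-state utility weights with plausible ranges.
states:
  pf_no_treatment:
    mean: 0.8872
    low: 0.525
    high: 1.0
  pf_rt:
    mean: 0.8239
    low: 0.425
    high: 0.995
  pf_rt_tmz:
    mean: 0.7426
    low: 0.175
    high: 0.98
  pf_rt_nt:
    mean: 0.7426
    low: 0.175
    high: 0.98
  pf_tmz_adjuvant:
    mean: 0.7331
    low: 0.175
    high: 0.99
  pf_nt_adjuvant:
    mean: 0.7331
    low: 0.175
    high: 0.99
  progressed:
    mean: 0.7314
    low: 0.125
    high: 0.995
progression_decrement_per_month: 0.02
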