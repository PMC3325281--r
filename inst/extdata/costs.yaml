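# Direct medical unit costs, 2009 USD (CNY converted at 6.50 per USD).
# Each item: point estimate with plausible range (low, high).
currency: USD
exchange_rate_cny_per_usd: 6.5
items:
  operation:
    mean: 5150
    low: 3680
    high: 6600
    unit: per procedure
  biopsy:
    mean: 1180
    low: 882
    high: 1470
    unit: per procedure
  rt_per_fraction:
    mean: 100
    low: 90
    high: 120
    unit: per 2 Gy fraction
  tmz_100mg:
    mean: 156
    low: 140
    high: 171
    unit: per 100 mg capsule
  tmz_20mg:
    mean: 38
    low: 34
    high: 41
    unit: per 20 mg capsule
  acnu_25mg:
    mean: 57
    low: 51
    high: 62
    unit: per 25 mg vial
  second_line_per_cycle:
    mean: 125
    low: 115
    high: 135
    unit: per 8-week PCV cycle (composite drug cost)
  supportive_care_per_cycle:
    mean: 735
    low: 480
    high: 1060
    unit: per monthly cycle
  follow_up_per_unit:
    mean: 90
    low: 70
    high: 120
    unit: per follow-up unit (MRI-dominated)
  sae_hematologic:
    mean: 321
    low: 289
    high: 353
    unit: per event
  sae_infection:
    mean: 588
    low: 529
    high: 647
    unit: per event
  sae_gastrointestinal:
    mean: 263
    low: 236
    high: 289
    unit: per event
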