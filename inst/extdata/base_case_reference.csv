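cohort,strategy,cost,qaly
overall,RT,7234.0,0.80
overall,RT+NT,8655.9,0.84
overall,RT+TMZ,32562.4,1.09
mgmt_methylated,RT,7753.3,1.12
mgmt_methylated,RT+NT,9500.0,1.27
mgmt_methylated,RT+TMZ,37598.2,1.47
mgmt_unmethylated,RT,7206.6,0.76
mgmt_unmethylated,RT+NT,8540.0,0.79
mgmt_unmethylated,RT+TMZ,31319.8,0.87
complete_resection,RT,7677.3,0.94
complete_resection,RT+NT,9678.5,1.02
complete_resection,RT+TMZ,34644.4,1.27
partial_resection,RT,7267.0,0.80
partial_resection,RT+NT,8703.3,0.84
partial_resection,RT+TMZ,28193.7,0.96
biopsy_only,RT,6074.1,0.57
biopsy_only,RT+NT,6855.1,0.61
biopsy_only,RT+TMZ,25598.8,0.73
age_lt50,RT,7672.3,0.87
age_lt50,RT+NT,9900.1,0.97
age_lt50,RT+TMZ,29351.4,1.16
age_50_60,RT,7374.4,0.82
age_50_60,RT+NT,8866.0,0.86
age_50_60,RT+TMZ,32182.4,1.02
age_gt60,RT,6990.5,0.78
age_gt60,RT+NT,8261.0,0.79
age_gt60,RT+TMZ,26388.8,0.86
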