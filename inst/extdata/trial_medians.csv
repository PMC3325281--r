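cohort,arm,endpoint,median,ci_low,ci_high
overall,RT,OS,12.1,11.2,13.0
overall,RT+TMZ,OS,14.6,13.2,16.8
mgmt_methylated,RT,OS,15.3,13.0,20.9
mgmt_methylated,RT+TMZ,OS,23.4,18.6,32.8
mgmt_unmethylated,RT,OS,11.8,10.0,14.4
mgmt_unmethylated,RT+TMZ,OS,12.6,11.6,14.4
complete_resection,RT,OS,14.2,12.1,16.1
complete_resection,RT+TMZ,OS,18.8,16.4,22.9
partial_resection,RT,OS,11.7,9.7,13.1
partial_resection,RT+TMZ,OS,13.5,11.9,16.4
biopsy_only,RT,OS,7.8,6.4,10.6
biopsy_only,RT+TMZ,OS,9.4,7.5,13.6
age_lt50,RT,OS,13.6,11.6,15.6
age_lt50,RT+TMZ,OS,17.4,15.3,21.5
age_50_60,RT,OS,12.0,10.0,14.2
age_50_60,RT+TMZ,OS,14.6,13.6,17.9
age_gt60,RT,OS,11.8,10.4,12.7
age_gt60,RT+TMZ,OS,10.9,8.9,14.9
overall,RT,PFS,5.0,4.2,5.5
overall,RT+TMZ,PFS,6.9,5.8,8.2
mgmt_methylated,RT,PFS,5.9,5.3,7.7
mgmt_methylated,RT+TMZ,PFS,10.3,6.5,14.0
mgmt_unmethylated,RT,PFS,4.4,3.1,6.0
mgmt_unmethylated,RT+TMZ,PFS,5.3,5.0,7.6
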