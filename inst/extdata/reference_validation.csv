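cancer_type,stratum,n,ppv_pct,ci_low_pct,ci_high_pct
hepatobiliary,S1_code_notes_support,NA,88.5,77.8,95.3
hepatobiliary,S2_code_notes,NA,86.8,71.9,95.6
hepatobiliary,S3_code_only,NA,80.0,59.3,93.2
hepatobiliary,weighted_mean,124,87.6,81.8,93.4
esophageal,S1_code_notes_support,NA,96.4,89.9,99.3
esophageal,S2_code_notes,NA,91.9,78.1,98.3
esophageal,S3_code_only,NA,100,NA,NA
esophageal,weighted_mean,152,96.2,93.1,99.2
pancreatic,S1_code_notes_support,NA,88.2,79.4,94.2
pancreatic,S2_code_notes,NA,94.7,82.3,99.4
pancreatic,S3_code_only,NA,89.7,72.6,97.8
pancreatic,weighted_mean,152,89.4,84.5,94.3
gastric,S1_code_notes_support,NA,94.0,86.5,98.0
gastric,S2_code_notes,NA,80.0,64.4,90.9
gastric,S3_code_only,NA,94.3,80.8,99.3
gastric,weighted_mean,158,92.5,88.3,96.6
colorectal,S1_code_notes_support,NA,96.0,90.0,98.9
colorectal,S2_code_notes,NA,89.5,75.2,97.1
colorectal,S3_code_only,NA,91.9,78.1,98.3
colorectal,weighted_mean,174,95.2,92.1,98.4
overall,S1_code_notes_support,NA,93.0,90.0,95.2
overall,S2_code_notes,NA,89.5,84.3,93.5
overall,S3_code_only,NA,91.7,86.3,95.5
overall,weighted_mean,760,92.4,90.5,94.3
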