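characteristic,category,n
total,all,12139
sex,male,5412
sex,female,6727
disease,hypertension,4805
disease,diabetes,1078
disease,heart disease,1971
disease,stroke,1300
disease,chronic lung disease,1227
disease,cancer,170
disease,chronic stomach disease,539
disease,parkinson's disease,88
disease,arthritis,1228
disease,dementia,262
disease,epilepsy,29
disease,cholelith disease,463
disease,dyslipidemia,587
disease,rheumatism,591
disease,chronic nephritis,130
disease,chronic hepatitis,51
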