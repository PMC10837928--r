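disease,degree_male,degree_female
hypertension,5532,3217
diabetes,2256,1310
heart disease,3750,2246
stroke,2543,1391
chronic lung disease,1887,904
cancer,369,218
chronic stomach disease,1132,701
parkinson's disease,215,121
arthritis,2576,1705
dementia,430,275
epilepsy,115,66
cholelith disease,1191,791
dyslipidemia,1726,1022
rheumatism,1288,868
chronic nephritis,467,237
chronic hepatitis,163,82
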