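category,icd9_pattern,match_type
mi,410,prefix
mi,412,prefix
chf,428,prefix
pvd,441,prefix
pvd,4439,prefix
pvd,7854,prefix
pvd,V434,prefix
cvd,430,prefix
cvd,431,prefix
cvd,432,prefix
cvd,433,prefix
cvd,434,prefix
cvd,435,prefix
cvd,436,prefix
cvd,437,prefix
cvd,438,prefix
dementia,290,prefix
copd,490,prefix
copd,491,prefix
copd,492,prefix
copd,493,prefix
copd,494,prefix
copd,495,prefix
copd,496,prefix
copd,500,prefix
copd,501,prefix
copd,502,prefix
copd,503,prefix
copd,504,prefix
copd,505,prefix
copd,5064,prefix
rheum,7100,prefix
rheum,7101,prefix
rheum,7104,prefix
rheum,7140,prefix
rheum,7141,prefix
rheum,7142,prefix
rheum,71481,prefix
rheum,725,prefix
pud,531,prefix
pud,532,prefix
pud,533,prefix
pud,534,prefix
mild_liver,5712,prefix
mild_liver,5714,prefix
mild_liver,5715,prefix
mild_liver,5716,prefix
dm,2500,prefix
dm,2501,prefix
dm,2502,prefix
dm,2503,prefix
dm,2507,prefix
dm_comp,2504,prefix
dm_comp,2505,prefix
dm_comp,2506,prefix
paralysis,342,prefix
paralysis,3441,prefix
renal,582,prefix
renal,5830,prefix
renal,5831,prefix
renal,5832,prefix
renal,5833,prefix
renal,5834,prefix
renal,5835,prefix
renal,5836,prefix
renal,5837,prefix
renal,585,prefix
renal,586,prefix
renal,5880,prefix
malignancy,140,prefix
malignancy,141,prefix
malignancy,142,prefix
malignancy,143,prefix
malignancy,144,prefix
malignancy,145,prefix
malignancy,146,prefix
malignancy,147,prefix
malignancy,148,prefix
malignancy,149,prefix
malignancy,150,prefix
malignancy,151,prefix
malignancy,152,prefix
malignancy,153,prefix
malignancy,154,prefix
malignancy,155,prefix
malignancy,156,prefix
malignancy,157,prefix
malignancy,158,prefix
malignancy,159,prefix
malignancy,160,prefix
malignancy,161,prefix
malignancy,162,prefix
malignancy,163,prefix
malignancy,164,prefix
malignancy,165,prefix
malignancy,166,prefix
malignancy,167,prefix
malignancy,168,prefix
malignancy,169,prefix
malignancy,170,prefix
malignancy,171,prefix
malignancy,172,prefix
malignancy,174,prefix
malignancy,175,prefix
malignancy,176,prefix
malignancy,177,prefix
malignancy,178,prefix
malignancy,179,prefix
malignancy,180,prefix
malignancy,181,prefix
malignancy,182,prefix
malignancy,183,prefix
malignancy,184,prefix
malignancy,185,prefix
malignancy,186,prefix
malignancy,187,prefix
malignancy,188,prefix
malignancy,189,prefix
malignancy,190,prefix
malignancy,191,prefix
malignancy,192,prefix
malignancy,193,prefix
malignancy,194,prefix
malignancy,1950,prefix
malignancy,1951,prefix
malignancy,1952,prefix
malignancy,1953,prefix
malignancy,1954,prefix
malignancy,1955,prefix
malignancy,1956,prefix
malignancy,1957,prefix
malignancy,1958,prefix
malignancy,200,prefix
malignancy,201,prefix
malignancy,202,prefix
malignancy,203,prefix
malignancy,204,prefix
malignancy,205,prefix
malignancy,206,prefix
malignancy,207,prefix
malignancy,208,prefix
severe_liver,5722,prefix
severe_liver,5723,prefix
severe_liver,5724,prefix
severe_liver,5725,prefix
severe_liver,5726,prefix
severe_liver,5727,prefix
severe_liver,5728,prefix
severe_liver,4560,prefix
severe_liver,4561,prefix
severe_liver,4562,prefix
mets,196,prefix
mets,197,prefix
mets,198,prefix
mets,1990,prefix
mets,1991,prefix
aids,042,prefix
aids,043,prefix
aids,044,prefix
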