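phecode,description,icd10_codes,exclude_range_lo,exclude_range_hi,parent_phecode,sex
200,Myeloproliferative disease,D47.1,200,208,NA,both
218,Uterine leiomyoma,D25,218,219,NA,female
244,Hypothyroidism,E03,240,246,NA,both
250,Diabetes mellitus,E14,249,251,NA,both
250.2,Type 2 diabetes,E11,249,251,250,both
272,Disorders of lipid metabolism,E78.9,270,279,NA,both
272.1,Hyperlipidemia,E78.5,270,279,272,both
272.11,Hypercholesterolemia,E78.0,270,279,272.1,both
272.3,Hyperglyceridemia,E78.1,270,279,272,both
280,Iron deficiency anemia,D50,280,285,NA,both
285,Other anemia,D64,280,285,NA,both
296,Mood disorders,F32;F33,295,302,NA,both
401,Hypertension,I10,401,405,NA,both
454,Varicose veins,I83.9,454,459,NA,both
454.1,Varicose veins of lower extremity,I83.0,454,459,454,both
530,Diseases of esophagus,K21,530,539,NA,both
571,Chronic liver disease and cirrhosis,K74,571,573,NA,both
735,Acquired foot deformities,M20,735,736,NA,both
740,Osteoarthrosis,M15;M19,740,741,NA,both
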