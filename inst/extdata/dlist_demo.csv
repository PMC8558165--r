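code,system,stream,category,subcategory,excluded_from_frequency
85.21,ICD9CM_PROC,HD,Surgery,Lumpectomy,FALSE
85.22,ICD9CM_PROC,HD,Surgery,Lumpectomy,FALSE
85.41,ICD9CM_PROC,HD,Surgery,Surgery,FALSE
85.43,ICD9CM_PROC,HD,Surgery,Surgery,FALSE
40.3,ICD9CM_PROC,HD,Surgery,Lymphadenectomy,FALSE
40.23,ICD9CM_PROC,HD,Surgery,Lymphadenectomy,FALSE
85.53,ICD9CM_PROC,HD,Surgery,Plastic surgery,FALSE
85.7,ICD9CM_PROC,HD,Surgery,Radical and reconstructive surgery,FALSE
99.25,ICD9CM_PROC,HD,Chemotherapy,,FALSE
92.29,ICD9CM_PROC,HD,Radiotherapy,,FALSE
85.11,ICD9CM_PROC,HD,Diagnosis and monitoring,Biopsy,FALSE
89.52,ICD9CM_PROC,HD,Diagnosis and monitoring,Cardiologic assessment,FALSE
87.37,ICD9CM_PROC,HD,Diagnosis and monitoring,High diagnostic,FALSE
87.44,ICD9CM_PROC,HD,Diagnosis and monitoring,Conventional radiology,FALSE
88.73,ICD9CM_PROC,HD,Diagnosis and monitoring,Ultrasonography,FALSE
99.28,ICD9CM_PROC,HD,Biologic therapy,,FALSE
99.04,ICD9CM_PROC,HD,Transfusion,,FALSE
174.9,ICD9CM_DIAG,HD,Diagnosis and monitoring,Diagnosis,FALSE
V58.11,ICD9CM_DIAG,HD,Chemotherapy,,FALSE
V58.0,ICD9CM_DIAG,HD,Radiotherapy,,FALSE
V66.7,ICD9CM_DIAG,HD,Support therapy,,FALSE
89.01,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Specialist examination,FALSE
87.37.1,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,High diagnostic,FALSE
88.73.2,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Ultrasonography,FALSE
87.44.1,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Conventional radiology,FALSE
85.11.1,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Biopsy,FALSE
89.52,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Cardiologic assessment,FALSE
93.39.1,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Physiatry,FALSE
91.36.5,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Genetic tests,FALSE
88.99.2,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Bone Densitometry,FALSE
92.24.1,OUTPATIENT_NATIONAL,OPS,Radiotherapy,,FALSE
99.25.1,OUTPATIENT_NATIONAL,OPS,Chemotherapy,,FALSE
93.57.1,OUTPATIENT_NATIONAL,OPS,Post-surgical procedure,,FALSE
99.23.1,OUTPATIENT_NATIONAL,OPS,Hormone therapy,,FALSE
99.29.1,OUTPATIENT_NATIONAL,OPS,Support therapy,,FALSE
94.3,OUTPATIENT_NATIONAL,OPS,Psychotherapy,,FALSE
86.86,OUTPATIENT_NATIONAL,OPS,Plastic surgery,,FALSE
99.03.1,OUTPATIENT_NATIONAL,OPS,Transfusion,,FALSE
90.62.2,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Standard blood test,TRUE
91.38.5,OUTPATIENT_NATIONAL,OPS,Diagnosis and monitoring,Genetic marker,TRUE
L02BA01,ATC,DP,Hormone therapy,,FALSE
L02BG04,ATC,DP,Hormone therapy,,FALSE
L02BG03,ATC,DP,Hormone therapy,,FALSE
H02AB02,ATC,DP,Cortisone,,FALSE
H02AB07,ATC,DP,Cortisone,,FALSE
A04AA01,ATC,DP,Antiemetic,,FALSE
N02AB03,ATC,DP,Analgesic,,FALSE
N02AA01,ATC,DP,Analgesic,,FALSE
L03AA02,ATC,DP,Myelopoietic growth factor,,FALSE
M05BA04,ATC,DP,Bisphosphonate,,FALSE
L01AA01,ATC,DP,Chemotherapic drug,,FALSE
B03XA01,ATC,DP,Hematopoietic growth factors,,FALSE
L01CD01,ATC,HP,Chemotherapy,,FALSE
L01XC03,ATC,HP,Biologic therapy,,FALSE
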