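category,subcategory,n_initial,pct_initial_printed,n_continuing,pct_continuing_printed,n_final,pct_final_printed
Diagnosis and monitoring,,90535,59.8,380107,92.4,22464,73.4
Diagnosis and monitoring,Specialist examination,39042,25.8,147315,35.8,10060,32.9
Diagnosis and monitoring,High diagnostic,12915,8.5,34454,8.4,4809,15.7
Diagnosis and monitoring,Ultrasonography,12371,8.2,68218,16.6,1319,4.3
Diagnosis and monitoring,Conventional radiology,9599,6.3,75889,18.4,2997,9.8
Diagnosis and monitoring,Biopsy,6798,4.5,10261,2.5,344,1.1
Diagnosis and monitoring,Cardiologic assessment,5736,3.8,28387,6.9,2126,6.9
Diagnosis and monitoring,Physiatry,1499,1.0,5929,1.4,631,2.1
Diagnosis and monitoring,Genetic tests,952,0.6,1427,0.3,115,0.4
Diagnosis and monitoring,Bone Densitometry,1623,1.1,8227,2.0,63,0.2
Radiotherapy,,41597,27.5,9210,2.2,2711,8.9
Chemotherapy,,9407,6.2,9323,2.3,3019,9.9
Post-surgical procedure,,3913,2.6,4503,1.1,546,1.8
Hormone therapy,,2580,1.7,2306,0.6,555,1.8
Support therapy,,1983,1.3,3591,0.9,942,3.1
Psychotherapy,,1018,0.7,1685,0.4,103,0.3
Plastic surgery,,268,0.2,672,0.2,5,0.0
Transfusion,,4,0.0,98,0.0,248,0.8
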