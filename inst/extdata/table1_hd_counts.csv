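category,subcategory,n_initial,pct_initial_printed,n_continuing,pct_continuing_printed,n_final,pct_final_printed
Surgery,,8021,67.6,2560,28.8,93,2.5
Surgery,Lumpectomy,4931,41.6,505,5.7,30,0.8
Surgery,Surgery,1826,15.4,260,2.9,31,0.8
Surgery,Lymphadenectomy,743,6.3,128,1.4,16,0.4
Surgery,Plastic surgery,433,3.6,1646,18.5,15,0.4
Surgery,Radical and reconstructive surgery,88,0.7,21,0.2,1,0.0
Chemotherapy,,2150,18.1,1668,18.7,900,24.2
Diagnosis and monitoring,,1397,11.8,4045,45.4,2195,59.1
Diagnosis and monitoring,Biopsy,356,3.0,342,3.8,49,1.3
Diagnosis and monitoring,Cardiologic assessment,340,2.9,1019,11.4,446,12.0
Diagnosis and monitoring,Diagnosis,269,2.3,961,10.8,541,14.6
Diagnosis and monitoring,High diagnostic,231,1.9,807,9.1,569,15.3
Diagnosis and monitoring,Conventional radiology,101,0.9,580,6.5,359,9.7
Diagnosis and monitoring,Ultrasonography,85,0.7,270,3.0,120,3.2
Diagnosis and monitoring,Invasive procedure,8,0.1,42,0.5,100,2.7
Diagnosis and monitoring,Other diagnostic procedure,7,0.1,30,0.3,11,0.3
Radiotherapy,,173,1.5,108,1.2,101,2.7
Support therapy,,78,0.7,319,3.6,348,9.4
Biologic therapy,,35,0.3,102,1.1,19,0.5
Transfusion,,12,0.1,98,1.1,58,1.6
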