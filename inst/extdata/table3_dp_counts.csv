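category,subcategory,n_initial,pct_initial_printed,n_continuing,pct_continuing_printed,n_final,pct_final_printed
Hormone therapy,,18947,63.5,93373,67.5,2451,14.1
Cortisone,,4246,14.2,15493,11.2,6684,38.3
Antiemetic,,2884,9.7,1579,1.1,844,4.8
Analgesic,,1568,5.3,12450,9.0,6860,39.3
Myelopoietic growth factor,,1115,3.7,435,0.3,166,1.0
Bisphosphonate,,928,3.1,14247,10.3,288,1.7
Chemotherapic drug,,136,0.5,722,0.5,94,0.5
Hematopoietic growth factors,,31,0.1,83,0.1,49,0.3
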