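"group","day","n_detected","n_consistent","sum_ugm3"
"ester",0,47,NA,52648
"ester",1,38,34,42713
"ester",3,31,24,705447
"ester",6,18,14,533
"ester",9,4,3,45.7
"alcohol",0,7,NA,140
"alcohol",1,5,4,364
"alcohol",3,8,3,1078
"alcohol",6,17,7,379789
"alcohol",9,16,16,4658
"aldehyde",0,3,NA,2918
"aldehyde",1,1,1,2959
"aldehyde",3,3,1,19054
"aldehyde",6,8,2,1338
"aldehyde",9,8,7,1022
"ketone",0,6,NA,6251
"ketone",1,4,4,7649
"ketone",3,5,2,589
"ketone",6,5,2,35
"ketone",9,4,4,73.9
"fatty_acid",0,3,NA,6390
"fatty_acid",1,1,1,4703
"fatty_acid",3,1,1,4319
"fatty_acid",6,2,1,516
"fatty_acid",9,2,1,212
"etc",0,15,NA,221
"etc",1,12,7,115
"etc",3,7,5,105
"etc",6,15,3,35.1
"etc",9,21,8,73.4
"all",0,81,NA,68569
"all",1,61,51,58503
"all",3,55,36,730593
"all",6,65,29,382245
"all",9,55,39,6086
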