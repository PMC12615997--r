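"race","age_group","age_group_index","era","cases","person_years","survival","survival_se"
"black","45-49",0,"pre_psa",176,8e+05,0.6275,0.03644
"black","50-54",1,"pre_psa",663,8e+05,0.5861,0.01913
"black","55-59",2,"pre_psa",1561,8e+05,0.5454,0.0126
"black","60-64",3,"pre_psa",2940,8e+05,0.5054,0.00922
"black","65-69",4,"pre_psa",4846,8e+05,0.4661,0.00717
"black","70-74",5,"pre_psa",6519,8e+05,0.4274,0.00613
"black","75-79",6,"pre_psa",7367,8e+05,0.3893,0.00568
"black","80-84",7,"pre_psa",7517,8e+05,0.3519,0.00551
"white","45-49",0,"pre_psa",600,6e+06,0.75,0.01768
"white","50-54",1,"pre_psa",2400,6e+06,0.72,0.00917
"white","55-59",2,"pre_psa",6000,6e+06,0.69,0.00597
"white","60-64",3,"pre_psa",12000,6e+06,0.66,0.00432
"white","65-69",4,"pre_psa",21000,6e+06,0.63,0.00333
"white","70-74",5,"pre_psa",30000,6e+06,0.6,0.00283
"white","75-79",6,"pre_psa",36000,6e+06,0.57,0.00261
"white","80-84",7,"pre_psa",39000,6e+06,0.54,0.00252
"black","45-49",0,"psa",282,8e+05,0.8138,0.02318
"black","50-54",1,"psa",1061,8e+05,0.7931,0.01244
"black","55-59",2,"psa",2498,8e+05,0.7727,0.00838
"black","60-64",3,"psa",4704,8e+05,0.7527,0.00629
"black","65-69",4,"psa",7753,8e+05,0.733,0.00502
"black","70-74",5,"psa",10431,8e+05,0.7137,0.00443
"black","75-79",6,"psa",11788,8e+05,0.6947,0.00424
"black","80-84",7,"psa",12027,8e+05,0.676,0.00427
"white","45-49",0,"psa",960,6e+06,0.875,0.01067
"white","50-54",1,"psa",3840,6e+06,0.86,0.0056
"white","55-59",2,"psa",9600,6e+06,0.845,0.00369
"white","60-64",3,"psa",19200,6e+06,0.83,0.00271
"white","65-69",4,"psa",33600,6e+06,0.815,0.00212
"white","70-74",5,"psa",48000,6e+06,0.8,0.00183
"white","75-79",6,"psa",57600,6e+06,0.785,0.00171
"white","80-84",7,"psa",62400,6e+06,0.77,0.00168
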