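variable,level,coded_value,n_total,n_dead
gender_male,Female,0,359,44
gender_male,Male,1,1811,879
age_gt33,<=33,0,1082,465
age_gt33,>33,1,1088,458
married,Single,0,1039,548
married,Married,1,1131,375
high_education,Low,0,2106,913
high_education,High,1,64,10
imprisonment,No,0,811,329
imprisonment,Yes,1,1359,594
drug_abuse,No,0,560,158
drug_abuse,Yes,1,1610,765
art,No,0,1178,784
art,Yes,1,992,139
employed,Unemployed,0,1259,484
employed,Employed,1,911,439
idu_transmission,Other,0,714,123
idu_transmission,IDU,1,1456,800
tb,No,0,697,425
tb,Yes,1,1473,498
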