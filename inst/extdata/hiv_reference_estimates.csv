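part,model,variable,label,coefficient,se,published_ratio,published_ci_lower,published_ci_upper,published_ratio_erratum
incidence,ph,intercept,Intercept,0.518,0.354,1.679,0.839,3.360,0
incidence,ph,age_gt33,Age (>33 / <=33),0.509,0.145,1.664,1.252,2.210,0
incidence,ph,gender_male,Gender (Male / Female),1.228,0.379,3.414,1.624,7.177,0
incidence,ph,married,Marital status (Married / Single),-0.327,0.138,0.721,0.550,0.945,0
incidence,ph,art,Antiretroviral therapy (Yes / No),-2.028,0.143,0.132,0.099,0.174,0
incidence,ph,tb,Tuberculosis infection (Yes / No),-0.147,0.183,0.863,0.603,1.236,0
incidence,ph,high_education,Education (High / Low),-1.218,0.419,0.296,0.130,0.672,0
incidence,ph,imprisonment,Imprisonment (Yes / No),-1.034,0.198,0.356,0.241,0.524,0
incidence,ph,drug_abuse,Drug abuse (Yes / No),-0.455,0.269,0.634,0.374,1.075,0
incidence,ph,employed,Occupational status (Employed / Unemployed),0.166,0.122,1.181,0.929,1.499,0
incidence,ph,idu_transmission,HIV transmission (IDU / Other),0.732,0.271,2.079,1.222,3.537,0
incidence,frailty,intercept,Intercept,0.544,0.305,1.723,0.948,3.132,0
incidence,frailty,age_gt33,Age (>33 / <=33),0.498,0.141,1.645,1.248,2.169,0
incidence,frailty,gender_male,Gender (Male / Female),1.214,0.335,3.367,1.746,6.492,0
incidence,frailty,married,Marital status (Married / Single),-0.309,0.144,0.734,0.554,0.974,0
incidence,frailty,art,Antiretroviral therapy (Yes / No),-2.035,0.159,0.131,0.096,0.178,0
incidence,frailty,tb,Tuberculosis infection (Yes / No),-0.147,0.153,0.863,0.640,1.165,0
incidence,frailty,high_education,Education (High / Low),-1.241,0.498,0.289,0.109,0.767,0
incidence,frailty,imprisonment,Imprisonment (Yes / No),-1.047,0.198,0.351,0.238,0.517,0
incidence,frailty,drug_abuse,Drug abuse (Yes / No),-0.444,0.281,0.641,0.370,1.113,0
incidence,frailty,employed,Occupational status (Employed / Unemployed),0.167,0.138,1.182,0.902,1.549,0
incidence,frailty,idu_transmission,HIV transmission (IDU / Other),0.720,0.262,2.054,1.229,3.433,0
latency,ph,age_gt33,Age (>33 / <=33),0.046,0.073,1.047,0.907,1.208,0
latency,ph,gender_male,Gender (Male / Female),-0.221,0.229,0.802,0.512,1.256,0
latency,ph,married,Marital status (Married / Single),-0.024,0.084,0.976,0.828,1.151,0
latency,ph,art,Antiretroviral therapy (Yes / No),-0.632,0.121,0.532,0.419,0.674,0
latency,ph,tb,Tuberculosis infection (Yes / No),0.252,0.073,1.287,1.115,1.485,0
latency,ph,high_education,Education (High / Low),-0.086,0.460,0.918,0.372,2.261,0
latency,ph,imprisonment,Imprisonment (Yes / No),-0.355,0.088,0.701,0.590,0.833,0
latency,ph,drug_abuse,Drug abuse (Yes / No),-0.143,0.107,0.867,0.703,1.069,0
latency,ph,employed,Occupational status (Employed / Unemployed),-0.003,0.075,0.997,0.861,1.155,0
latency,ph,idu_transmission,HIV transmission (IDU / Other),0.705,0.151,2.024,1.505,2.721,0
latency,frailty,age_gt33,Age (>33 / <=33),0.115,0.094,1.122,0.933,1.349,0
latency,frailty,gender_male,Gender (Male / Female),-0.227,0.293,0.770,0.449,1.415,1
latency,frailty,married,Marital status (Married / Single),-0.093,0.103,0.911,0.745,1.115,0
latency,frailty,art,Antiretroviral therapy (Yes / No),-0.780,0.152,0.458,0.340,0.617,0
latency,frailty,tb,Tuberculosis infection (Yes / No),0.330,0.094,1.391,1.157,1.672,0
latency,frailty,high_education,Education (High / Low),-0.052,0.491,0.949,0.363,2.485,0
latency,frailty,imprisonment,Imprisonment (Yes / No),-0.466,0.108,0.628,0.508,0.775,0
latency,frailty,drug_abuse,Drug abuse (Yes / No),-0.171,0.162,0.843,0.614,1.158,0
latency,frailty,employed,Occupational status (Employed / Unemployed),-0.027,0.096,0.973,0.806,1.175,0
latency,frailty,idu_transmission,HIV transmission (IDU / Other),0.888,0.195,2.430,1.658,3.562,0
frailty,frailty,psi,Frailty variance,0.380,0.066,NA,0.249,0.510,0
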