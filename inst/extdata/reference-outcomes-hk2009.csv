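strategy,cost,inc_cost,ly,inc_ly,qaly,inc_qaly
No Screening,2541,0,15.6420,0,14.7479,0
Biennial G-FOBT,4221,1681,15.6862,0.0443,15.0687,0.3207
Annual G-FOBT,5394,2853,15.7104,0.0684,15.2339,0.4860
Colonoscopy every 10 years,4752,2212,15.7385,0.0965,15.3586,0.6106
Biennial I-FOBT,4542,2001,15.7429,0.1009,15.4203,0.6724
Annual I-FOBT,5068,2528,15.7650,0.1231,15.5491,0.8012
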