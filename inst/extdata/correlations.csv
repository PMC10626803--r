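variable,hemisphere,r,n,k,printed_p
bmi,left,-0.083,56,2,0.551
bmi,right,-0.014,56,2,0.922
disease_duration,left,0.189,48,2,0.209
disease_duration,right,0.181,48,2,0.229
age_of_onset,left,-0.190,48,2,0.206
age_of_onset,right,-0.181,48,2,0.229
vas,left,0.371,48,2,0.011
vas,right,0.307,48,2,0.038
attack_frequency,left,0.081,48,2,0.592
attack_frequency,right,0.137,48,2,0.363
midas,left,0.165,48,2,0.272
midas,right,0.125,48,2,0.408
hit6,left,-0.094,48,2,0.534
hit6,right,0.009,48,2,0.955
phq9,left,0.243,48,2,0.104
phq9,right,0.107,48,2,0.479
gad7,left,0.192,48,2,0.201
gad7,right,0.192,48,2,0.201
psqi,left,0.013,48,2,0.934
psqi,right,0.094,48,2,0.533
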