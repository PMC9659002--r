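variable,acronym,priority_vector,weight
Disease burden,DB,0.0159,0.0159
Tuberculosis,TB,0.0184,0.0184
Unsafe water source,UWS,0.0253,0.0253
Unsafe sanitation,USN,0.0175,0.0175
No access to handwashing facility,NHF,0.0107,0.0107
Household air pollution from solid fuels,HAP,0.0168,0.0168
Non-exclusive breastfeeding,NEB,0.0131,0.0131
Discontinued breastfeeding,DBF,0.0144,0.0144
Child wasting,CW,0.0103,0.0103
Child stunting,CS,0.0090,0.0090
Low birth weight due to short gestation,LBW,0.0067,0.0067
Secondhand smoke,SHS,0.0827,0.0827
Alcohol use,AU,0.0143,0.0143
Drug use,DU,0.0108,0.0108
Diet low in fruits,DLF,0.0206,0.0206
Diet low in vegetables,DLV,0.0207,0.0207
Unsafe sex,USX,0.0262,0.0262
Low physical activity,LPA,0.0220,0.0220
High fasting plasma glucose,HFP,0.0202,0.0202
High body-mass index,HBM,0.0202,0.0202
High systolic blood pressure,HBP,0.0205,0.0205
Iron deficiency,IDY,0.1288,0.1288
Smoking,Smoking,0.0148,0.0148
Vitamin A deficiency,VAD,0.0146,0.0146
Low bone mineral density,LBD,0.0368,0.0368
Air pollution,AP,0.1420,0.1420
Outdoor air pollution,OAP,0.1665,0.1665
Diet high in sodium,DHS,0.0384,0.0384
Diet low in whole grains,DLG,0.0257,0.0257
Diet low in nuts and seeds,DLN,0.0160,0.0160
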