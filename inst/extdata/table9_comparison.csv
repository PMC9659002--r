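variable,acronym,rfm_rank,ahp_weight,ahp_rank,chisq_weight,chisq_rank,ridit_weight,ridit_rank
Smoking,Smoking,1,0.015,3,0.042,3,0.002,24
Low physical activity,LPA,2,0.022,10,0.037,9,0.013,18
Child Wasting,CW,3,0.010,22,0.047,1,0.032,8
Low birth weight due to short gestation,LBW,4,0.007,24,0.042,4,0.023,13
Iron deficiency,IDY,5,0.129,18,0.020,22,0.067,3
Diet low in nuts and seeds,DLN,6,0.016,16,0.034,13,0.021,16
Vitamin A deficiency,VAD,7,0.015,19,0.043,2,0.008,20
Low bone mineral density,LBD,8,0.037,6,0.034,15,0.003,23
Air pollution,AP,9,0.142,2,0.027,20,0.040,6
Diet high in sodium,DHS,10,0.038,5,0.034,14,0.024,12
Household air pollution from solid fuels,HAP,11,0.017,15,0.036,11,0.025,11
Diet low in fruits,DLF,12,0.021,12,0.035,12,0.021,15
Disease burden,DB,13,0.016,17,0.003,24,0.245,1
Diet low in vegetables,DLV,14,0.021,11,0.037,10,0.014,17
Alcohol use,AU,15,0.014,20,0.033,17,0.033,7
Drug use,DU,16,0.011,21,0.038,6,0.006,22
High body-mass index,HBM,17,0.020,13,0.024,21,0.054,4
Child stunting,CS,18,0.009,23,0.039,5,0.007,21
Unsafe water source,UWS,19,0.025,9,0.038,7,0.023,14
High fasting plasma glucose,HFP,20,0.020,14,0.018,23,0.070,2
Diet low in whole grains,DLG,21,0.026,8,0.031,19,0.031,9
Outdoor air pollution,OAP,22,0.167,1,0.033,16,0.025,10
Unsafe sex,USX,23,0.026,7,0.032,18,0.048,5
Secondhand smoke,SHS,24,0.083,4,0.038,8,0.010,19
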