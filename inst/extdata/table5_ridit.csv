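variable,acronym,ridit_value,ridit_weight
Disease burden,DB,0.247,0.244
Tuberculosis,TB,0.018,0.018
Unsafe water source,UWS,0.020,0.020
Unsafe sanitation,USN,0.015,0.015
No access to handwashing facility,NHF,0.014,0.014
Household air pollution from solid fuels,HAP,0.024,0.024
Non-exclusive breastfeeding,NEB,0.004,0.004
Discontinued breastfeeding,DBF,0.001,0.000
Child wasting,CW,0.028,0.028
Child stunting,CS,0.006,0.006
Low birth weight due to short gestation,LBW,0.021,0.021
Secondhand smoke,SHS,0.011,0.011
Alcohol use,AU,0.034,0.034
Drug use,DU,0.006,0.006
Diet low in fruits,DLF,0.022,0.022
Diet low in vegetables,DLV,0.015,0.015
Unsafe sex,USX,0.041,0.041
Low physical activity,LPA,0.014,0.014
High fasting plasma glucose,HFP,0.076,0.076
High body-mass index,HBM,0.057,0.057
High systolic blood pressure,HBP,0.107,0.106
Iron deficiency,IDY,0.072,0.071
Smoking,Smoking,0.001,0.001
Vitamin A deficiency,VAD,0.007,0.007
Low bone mineral density,LBD,0.003,0.003
Air pollution,AP,0.043,0.043
Outdoor air pollution,OAP,0.027,0.026
Diet high in sodium,DHS,0.024,0.024
Diet low in whole grains,DLG,0.032,0.032
Diet low in nuts and seeds,DLN,0.022,0.022
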