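variable,acronym,chisq,weight
Disease burden,DB,41.37,0.0030
Tuberculosis,TB,516.68,0.0372
Unsafe water source,UWS,523.82,0.0377
Unsafe sanitation,USN,533.08,0.0384
No access to handwashing facility,NHF,532.60,0.0383
Household air pollution from solid fuels,HAP,497.60,0.0358
Non-exclusive breastfeeding,NEB,553.70,0.0399
Discontinued breastfeeding,DBF,581.37,0.0418
Child wasting,CW,646.50,0.0465
Child stunting,CS,545.02,0.0392
Low birth weight due to short gestation,LBW,581.04,0.0418
Secondhand smoke,SHS,522.60,0.0376
Alcohol use,AU,451.03,0.0325
Drug use,DU,531.80,0.0383
Diet low in fruits,DLF,491.40,0.0354
Diet low in vegetables,DLV,506.60,0.0365
Unsafe sex,USX,449.78,0.0324
Low physical activity,LPA,514.90,0.0371
High fasting plasma glucose,HFP,246.80,0.0178
High body-mass index,HBM,331.50,0.0239
High systolic blood pressure,HBP,160.50,0.0116
Iron deficiency,IDY,281.30,0.0202
Smoking,Smoking,586.03,0.0422
Vitamin A deficiency,VAD,595.18,0.0428
Low bone mineral density,LBD,470.50,0.0339
Air pollution,AP,370.06,0.0266
Outdoor air pollution,OAP,453.13,0.0326
Diet high in sodium,DHS,473.13,0.0341
Diet low in whole grains,DLG,429.40,0.0309
Diet low in nuts and seeds,DLN,475.24,0.0342
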