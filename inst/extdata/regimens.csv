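drug,regimen_class,route,dose_mg_per_kg,infusion_min,loading_mg_per_kg
acetaminophen,short,IV,15,10,NA
raclopride,short,IV,0.56,10,NA
morphine,short,IV,40,10,NA
paliperidone,short,IV,0.5,20,NA
quinidine,short,IV,20,10,NA
risperidone,short,SC,3,0,NA
paliperidone,continuous,IV,4,240,0.8
quinidine,continuous,IV,20,240,8.0
risperidone,continuous,IV,4,240,0.7
verapamil,continuous,IV,4,240,0.9
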