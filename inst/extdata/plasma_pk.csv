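drug,regimen_class,cl_cen,q_cen_per1,q_cen_per2,v_cen,v_per1,v_per2,ka,ambiguous
acetaminophen,short,4.71,1.23,1.45,0.727,892,162.5,NA,TRUE
raclopride,short,47.7,16.5,56.8,83,603,457.5,NA,TRUE
morphine,short,22.6,30.8,7.2,152,530,1200,NA,TRUE
paliperidone,short,219.56,766,0,253,2981,0,NA,TRUE
quinidine,short,178.3,238,754,1847,3355,63,NA,TRUE
risperidone,short,77,0,0,5250,0,0,0.03,FALSE
paliperidone,continuous,29.2,0,0,2053,0,0,NA,FALSE
quinidine,continuous,250,0,0,7314,0,0,NA,FALSE
risperidone,continuous,370,0,0,3799,0,0,NA,FALSE
verapamil,continuous,72.3,0,0,11700,0,0,NA,FALSE
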