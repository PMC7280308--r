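scope,id,parameter,value,unit,provenance
boundary,G1P,value,0.10000000000000001,mM,literature
boundary,GLC_EXT,value,5,mM,literature
boundary,GLYC_SINK,value,0,mM,literature
boundary,LAC_EXT,value,0,mM,literature
boundary,PPP_SINK,value,0,mM,literature
boundary,TCA_SINK,value,0,mM,literature
coupling,ENO,K_Eh,0.0018505508545171255,level/(uM*min),calibrated
coupling,ENO,sign,1,dimensionless,literature
coupling,GAPDH,K_Eh,0.0012057566993365005,level/(uM*min),calibrated
coupling,GAPDH,sign,1,dimensionless,literature
coupling,GLUT,K_Eh,1.6666666666666667e-05,level/(uM*min),calibrated
coupling,GLUT,sign,1,dimensionless,literature
coupling,HK,K_Eh,0.0011386949946127259,level/(uM*min),calibrated
coupling,HK,sign,1,dimensionless,literature
coupling,LDH,K_Eh,0.0042091320771943689,level/(uM*min),calibrated
coupling,LDH,sign,1,dimensionless,literature
coupling,PDK,K_Eh,0.00040000000000000002,level/(uM*min),calibrated
coupling,PDK,sign,1,dimensionless,literature
coupling,PFK1,K_Eh,0.0018471780742226607,level/(uM*min),calibrated
coupling,PFK1,sign,1,dimensionless,literature
coupling,PGCM,K_Eh,0.0018471780742226607,level/(uM*min),calibrated
coupling,PGCM,sign,1,dimensionless,literature
coupling,PGI,K_Eh,0.0029554849187562572,level/(uM*min),calibrated
coupling,PGI,sign,1,dimensionless,literature
coupling,PGK,K_Eh,0.0035221866183213837,level/(uM*min),calibrated
coupling,PGK,sign,1,dimensionless,literature
coupling,PGM,K_Eh,0.0013645779759267399,level/(uM*min),calibrated
coupling,PGM,sign,1,dimensionless,literature
coupling,TPI,K_Eh,0.0030000000000000001,level/(uM*min),calibrated
coupling,TPI,sign,1,dimensionless,literature
oxygen_map,map,H_basal,0,uM,calibrated
oxygen_map,map,H_max,1,uM,calibrated
oxygen_map,map,hill_n,2.7999999999999998,dimensionless,calibrated
oxygen_map,map,o2_half,1.2,percent,calibrated
pdh_cycle,PDH,k_pdk,1,1/min,database
pdh_cycle,PDH,k_pdp,0.5,1/min,database
pdh_cycle,PDH,total,3,level,calibrated
reaction,ACOX,k,56.666666666666664,1/min,calibrated
reaction,ALDO,Kp,0.10000000000000001,mM,database
reaction,ALDO,Ks,0.5,mM,database
reaction,ALDO,Vf,190.79647774048874,mM/min,calibrated
reaction,ALDO,Vr,171.71682996643986,mM/min,calibrated
reaction,ENO,Kp,0.59999999999999998,mM,database
reaction,ENO,Ks,0.25,mM,database
reaction,ENO,Vf,62.167627793129327,mM/min,calibrated
reaction,ENO,Vr,11.190173002763281,mM/min,calibrated
reaction,G3PS,k,10.666666666666668,1/min,calibrated
reaction,GAPDH,Kp,2,mM,database
reaction,GAPDH,Ks,0.25,mM,database
reaction,GAPDH,Vf,49.056984066288834,mM/min,calibrated
reaction,GAPDH,Vr,19.622793626515534,mM/min,calibrated
reaction,GLUT,Kp,20,mM,database
reaction,GLUT,Ks,0.29999999999999999,mM,database
reaction,GLUT,Vf,7.1628197357552734,mM/min,calibrated
reaction,GLUT,Vr,47.752131571701824,mM/min,calibrated
reaction,HK,Km,1,mM,database
reaction,HK,Vmax,13.207080604026656,mM/min,calibrated
reaction,LACX,k,0.95531459435099919,1/min,calibrated
reaction,LDH,Kp,10,mM,database
reaction,LDH,Ks,0.29999999999999999,mM,database
reaction,LDH,Vf,44.013636116776986,mM/min,calibrated
reaction,LDH,Vr,7.7762607980171348,mM/min,calibrated
reaction,PDH,Km,0.01,mM,database
reaction,PDH,Vmax,3.7399999999999998,mM/min,calibrated
reaction,PFK1,Km,1,mM,database
reaction,PFK1,Vmax,39.893808982102172,mM/min,calibrated
reaction,PGCM,Km,0.050000000000000003,mM,database
reaction,PGCM,Vmax,1.8,mM/min,calibrated
reaction,PGI,Kp,0.20000000000000001,mM,database
reaction,PGI,Ks,0.59999999999999998,mM,database
reaction,PGI,Vf,46.088499817832329,mM/min,calibrated
reaction,PGI,Vr,33.286138757323357,mM/min,calibrated
reaction,PGK,Kp,2,mM,database
reaction,PGK,Ks,0.29999999999999999,mM,database
reaction,PGK,Vf,68.499515809096195,mM/min,calibrated
reaction,PGK,Vr,6.8499515809096199,mM/min,calibrated
reaction,PGM,Kp,0.29999999999999999,mM,database
reaction,PGM,Ks,1.2,mM,database
reaction,PGM,Vf,47.661847974732488,mM/min,calibrated
reaction,PGM,Vr,11.915461993683122,mM/min,calibrated
reaction,PK,Km,1.5,mM,database
reaction,PK,Vmax,118.89558815435986,mM/min,calibrated
reaction,PPP,Km,5,mM,database
reaction,PPP,Vmax,28.600000000000001,mM/min,calibrated
reaction,TPI,Kp,0.014999999999999999,mM,database
reaction,TPI,Ks,0.02,mM,database
reaction,TPI,Vf,40.039336689036979,mM/min,calibrated
reaction,TPI,Vr,63.812692848152672,mM/min,calibrated
species,ACCOA,initial,0.059999999999999998,mM,literature
species,BPG13,initial,0.059999999999999998,mM,literature
species,DHAP,initial,0.14999999999999999,mM,literature
species,ENO,initial,1,level,literature
species,F6P,initial,0.14999999999999999,mM,literature
species,FBP,initial,0.29999999999999999,mM,literature
species,G6P,initial,0.5,mM,literature
species,GA3P,initial,0.059999999999999998,mM,literature
species,GAPDH,initial,1,level,literature
species,GLC,initial,1,mM,literature
species,GLUT,initial,1,level,literature
species,HK,initial,1,level,literature
species,LAC,initial,5.6600000000000001,mM,literature
species,LDH,initial,1,level,literature
species,PDHA,initial,1,level,literature
species,PDK,initial,1,level,literature
species,PEP,initial,0.12,mM,literature
species,PFK1,initial,1,level,literature
species,PG2,initial,0.059999999999999998,mM,literature
species,PG3,initial,0.40000000000000002,mM,literature
species,PGCM,initial,1,level,literature
species,PGI,initial,1,level,literature
species,PGK,initial,1,level,literature
species,PGM,initial,1,level,literature
species,PYR,initial,0.10000000000000001,mM,literature
species,TPI,initial,1,level,literature
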