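label,study,role,classification,act_vhalf_mv,act_k_mv,fast_vhalf_mv,fast_k_mv,slow_vhalf_mv,slow_k_mv,tau_slow_exp_ms,tau_slow_model_ms,tau_slow_at_mv,recovery_phenotype,condition
L263V,L263V,mutant,gain,-24.6,7.1,-54.4,6.7,-54.1,5.0,3507,3500,-10,none,FHM3
WT_L263V,L263V,wt,wt,-21.5,7.2,-62.2,6.4,-66.8,6.3,2100,2100,-10,none,FHM3
Q1478K,Q1478K,mutant,combined,-24.8,9.1,-60.1,7.4,-77.2,7.7,938,940,-5,fast_h,FHM3
WT_Q1478K,Q1478K,wt,wt,-24.5,7.9,-65.1,6.0,-75.8,6.2,2090,2100,-5,none,FHM3
L1649Q,L1649Q,mutant,gain,-22.9,7.4,-34.5,7.1,-57.7,8.9,1885,1885,0,fast_s,FHM3
WT_L1649Q,L1649Q,wt,wt,-21.0,6.6,-54.2,5.5,-59.7,9.7,2616,2600,0,none,FHM3
L1670W,L1670W,mutant,gain,-16.8,6.1,-47.3,6.1,-34.8,10.0,2070,2070,-10,fast_h,FHM3
WT_L1670W,L1670W,wt,wt,-21.6,6.6,-55.6,4.9,-53.5,7.6,1310,1300,-10,none,FHM3
M145T,M145T,mutant,loss,-11.7,7.1,-65.5,9.1,NA,NA,NA,NA,NA,none,familial simple febrile seizures
WT_M145T,M145T,wt,wt,-21.7,6.15,-64.9,8.0,NA,NA,NA,NA,NA,none,familial simple febrile seizures
R1648H,R1648H,mutant,gain,-19.9,8.5,-61.3,7.8,-68.6,6.1,3112,3112,-10,none,GEFS+
WT_R1648H,R1648H,wt,wt,-19.4,7.9,-62.7,6.9,-66.7,7.8,3029,3000,-10,none,GEFS+
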