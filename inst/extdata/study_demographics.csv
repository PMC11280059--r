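study_id,reference,subgroup,female_fraction,age_min,age_max,population,route,doses_mg,n_subjects,weight_mean_kg,weight_sd_kg
1,B30,NA,0.45,18,45,healthy,PO,50,11,68.1,7.1
1,B30,NA,0.45,18,45,healthy,IV,25,11,68.1,7.1
2,B35,NA,0.48,18,45,healthy,PO,25;50;100;200,60,58.6,5.6
3,B38,NA,0.65,18,45,healthy,PO,25;50;100;200,20,70.9,8.6
4,B37,NA,0.00,18,45,healthy,PO,100,4,85,NA
5,B36,mild,0.56,18,85,ckd,PO,50,96,63.1,NA
5,B36,moderate,0.62,18,85,ckd,PO,50,96,62.4,NA
5,B36,severe,0.61,18,85,ckd,PO,50,96,63.7,NA
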