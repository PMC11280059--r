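section,parameter,literature_value,input_value,unit,note
physicochemical,binding_protein,albumin,albumin,,
physicochemical,molecular_weight,303.4,303.4,g/mol,
physicochemical,water_solubility,60,60,mg/mL at pH 7,
physicochemical,pka_base,9.7,9.7,,
physicochemical,logp,1.12,1.55,,manually optimized
absorption,intestinal_permeability,5e-4,5e-4,cm/s,
absorption,formulation_method,Weibull,Weibull,,
absorption,dissolution_t50,50,50,min,optimized
distribution,fu_plasma,0.907,0.907,fraction,
distribution,partition_model,Poulin-Theil,Poulin-Theil,,
distribution,cellular_permeability_model,standard,standard,,
metabolism,km_umol_l,190,190,umol/L,
metabolism,vmax_nmol_l_s,23.31,23.31,nmol/L/s,
excretion,renal_clearance,13,13,L/h,0.18 L/h/kg
disease,egfr_healthy,>60,,mL/min,
disease,egfr_moderate,48,48,mL/min,
disease,egfr_severe,29,29,mL/min,
disease,gastric_emptying_healthy,15,15,min,
disease,gastric_emptying_moderate,20.63,20.63,min,
disease,gastric_emptying_severe,39,39,min,
disease,git_transit_healthy,2.1,2.1,h,
disease,git_transit_moderate,2.94,2.94,h,
disease,git_transit_severe,4.12,4.12,h,
disease,hematocrit_healthy,0.47,0.47,fraction,
disease,hematocrit_moderate,0.42,0.42,fraction,
disease,hematocrit_severe,0.37,0.37,fraction,
disease,protein_scaling_moderate,0.93,0.93,factor,
disease,protein_scaling_severe,0.83,0.83,factor,
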