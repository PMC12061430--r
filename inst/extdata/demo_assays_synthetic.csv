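assay_id,source,perturb_node,perturb_mode,perturb_level,environment,control_environment,initial_environment,readout,direction,window,steps,contradictory
hypoxia_emt,synthA,NA,none,0,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,ZEB1,increase,1,50,FALSE
hypoxia_emt,synthA,NA,none,0,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,Ecadherin,decrease,1,50,FALSE
hypoxia_arrest,synthA,NA,none,0,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,CellCycle,decrease,1,50,FALSE
tgfbr_ko_emt,synthB,TGFbR,off,1,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,ZEB1,no-change,1,50,FALSE
vhl_oe_emt,synthB,VHL,on,1,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,ZEB1,no-change,1,50,FALSE
vhl_ko_emt,synthC,VHL,off,1,GF=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,ZEB1,increase,1,50,FALSE
vhl_ko_arrest,synthC,VHL,off,1,GF=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,CellCycle,decrease,1,50,FALSE
hif_high_arrest,synthD,Hif1a_High,on,1,GF=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,CellCycle,decrease,1,50,FALSE
hif_basal_prolif,synthD,Hif1a_basal,off,1,GF=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,CellCycle,decrease,1,50,FALSE
tgfb_soft_apoptosis,synthE,NA,none,0,GF=1;TGFb_ext=1;ECM_attached=1,GF=1;ECM_attached=1,ECM_attached=1,Apoptosis,increase,1,50,FALSE
hypoxia_tgfb_protect,synthE,NA,none,0,GF=1;TGFb_ext=1;Hypoxia=1;ECM_attached=1,GF=1;TGFb_ext=1;ECM_attached=1,ECM_attached=1,Apoptosis,decrease,1,50,FALSE
density_blocks_emt,synthF,NA,none,0,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1;Density_High=1,GF=1;Hypoxia=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1;Density_High=1,ZEB1,decrease,1,50,FALSE
myc_ko_prolif,synthF,Myc,off,1,GF=1;Stiff_ECM=1;ECM_attached=1,GF=1;Stiff_ECM=1;ECM_attached=1,Stiff_ECM=1;ECM_attached=1,CellCycle,decrease,1,50,FALSE
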