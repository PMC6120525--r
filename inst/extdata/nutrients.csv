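species,system,protein_g_per_100g,mufa_g_per_100g,epa_dha_mg_per_100g,ca_mg_per_100g,fe_mg_per_100g,riboflavin_mg_per_100g,folate_ug_per_100g,vitamin_b12_ug_per_100g,se_ug_per_100g,zn_mg_per_100g,na_g_per_100g,sfa_g_per_100g
beef,concentrate,23.5,1.1,3.4,5,1.6,0.26,16,2,8,4,0.07,1.1
beef,forage,23.5,1.6,27.4,5,1.6,0.26,16,2,8,4,0.07,1.5
lamb,lowland,20,1.3,26.4,12,1.4,0.2,6,1,3,2,0.07,1.3
lamb,upland,20,1.1,31.7,12,1.4,0.2,6,1,3,2,0.07,1.2
chicken,intensive,26.3,3.7,17.6,11,0.7,0.15,9,0,15,1.5,0.08,2.4
chicken,free_range,26.3,5.4,14.7,11,0.7,0.15,9,0,15,1.5,0.08,3.7
pork,intensive,18.6,0.9,14.8,10,0.4,0.18,1,1,11,1.3,0.053,0.9
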