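species,system,gwp_value,gwp_basis,kill_out_fraction,meat_per_carcass_fraction,omega3_mg_per_100g,epa_dha_mg_per_100g,omega6_omega3_ratio
beef,concentrate,7.9,carcass,1.0,0.87,20.3,3.4,14.4
beef,forage,15.9,carcass,1.0,0.87,97.2,27.4,1.2
lamb,lowland,10.9,liveweight,0.474,0.88,94.0,26.4,1.2
lamb,upland,12.9,liveweight,0.474,0.88,103,31.7,1.5
chicken,intensive,4.4,edible_meat,1.0,1.0,362,17.6,5.5
chicken,free_range,5.1,edible_meat,1.0,1.0,214,14.7,7.6
pork,intensive,4.0,carcass,1.0,0.54,51.3,14.8,7.4
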