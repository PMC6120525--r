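species,system,gwp_mass_basis
beef,concentrate,9.8
beef,forage,18.3
lamb,lowland,26.1
lamb,upland,30.9
chicken,intensive,4.4
chicken,free_range,5.1
pork,intensive,7.4
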