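nutrient,value,unit,role
protein,50.25,g,encouraged
mufa,37.5,g,encouraged
epa_dha,250,mg,encouraged
ca,700,mg,encouraged
fe,11.75,mg,encouraged
riboflavin,1.2,mg,encouraged
folate,200,ug,encouraged
vitamin_b12,1.5,ug,encouraged
se,67.5,ug,encouraged
zn,8.25,mg,encouraged
na,6,g,limited
sfa,25,g,limited
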