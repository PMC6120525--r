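# UKNI index specifications: qualifying nutrients are rewarded, disqualifying
# nutrients (the limit nutrients SFA and sodium) are penalised.
- name: UKNIprot7
  qualifying: [protein, mufa, epa_dha, ca, fe, riboflavin, folate]
  disqualifying: []
- name: UKNIprot7-2
  qualifying: [protein, mufa, epa_dha, ca, fe, riboflavin, folate]
  disqualifying: [sfa, na]
- name: UKNIprot10
  qualifying: [protein, mufa, epa_dha, ca, fe, riboflavin, folate, vitamin_b12, se, zn]
  disqualifying: []
- name: UKNIprot10-2
  qualifying: [protein, mufa, epa_dha, ca, fe, riboflavin, folate, vitamin_b12, se, zn]
  disqualifying: [sfa, na]
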