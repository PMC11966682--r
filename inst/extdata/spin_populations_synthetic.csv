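site,population,conformer
Fe1,3.07,A
Fe2,3.12,A
Fe3,-2.91,A
Fe4,-2.96,A
Fe1,-2.89,B
Fe2,3.05,B
Fe3,3.10,B
Fe4,-2.93,B
Fe1,2.98,C
Fe2,-2.90,C
Fe3,-2.94,C
Fe4,3.08,C
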