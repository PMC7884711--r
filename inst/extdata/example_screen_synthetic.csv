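id,sequence,intensity_au,max_od_pct,source
ex_01,GRKKRRQRRRPPQ,3815.2,95.4,cppsite
ex_02,RRRRRRRRR,2901.7,88.1,cppsite
ex_03,rrrrrrrrrcqcrrkn,1210.3,72.6,cppsite
ex_04,KLPVM,41.8,101.2,literature
ex_05,KLWRPLFAVKLM,26.5,31.9,literature
ex_06,RKKRRHRRRKE,1650.0,,manual
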