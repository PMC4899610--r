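antioxidant,rate_nM_min,rate_sd_nM_min,chain_length,inhibition_efficiency,inhibition_duration_min,duration_sd_min,conc_uM
pure CL,334,32,28,NA,NA,NA,NA
decPQH2,3.28,1.1,0.28,102,48.7,2.1,1
SkQ1H2,3.87,0.6,0.33,86,58.7,5.7,1
decUQH2,4.49,1.2,0.38,74,114,4.4,1
MitoQH2,6.70,2.0,0.57,50,91,8.9,1
Q6H2,4.05,0.5,0.34,82,124,9,1
Q10H2,4.55,0.4,0.39,73,104,1,1
alpha-tocopherol,10.6,0.5,0.90,32,171,1,1
HPMC,8.62,1.8,0.73,39,NA,NA,1
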