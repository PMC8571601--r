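scenario,year,suitable_km2,optimal_km2
current,NA,32593.1,10729.4
RCP2.6,2050,11912.3,2961
RCP4.5,2050,11118.6,1524.3
RCP6.0,2050,5403.8,796.3
RCP8.5,2050,9129.6,2591
RCP2.6,2070,5727.7,482.7
RCP4.5,2070,4568,446
RCP6.0,2070,3217.7,213.3
RCP8.5,2070,3718.6,321.2
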