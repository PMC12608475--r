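name,delta_d,delta_p,delta_hb,ro,source
cutin,19.7,5.4,2.5,hexane,five-solvent swelling estimate (this package)
PLA,17.9,9.2,5.9,,literature HSP; Ro not shipped - supply a number or reference solvent
PHB,NA,NA,NA,,placeholder - user must supply HSP and Ro
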