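wavelength_nm,absorbance
400,0.055
550,0.015
700,0.011
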