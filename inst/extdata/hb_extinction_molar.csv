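wavelength_nm,chromophore,epsilon_per_cm_per_M
670,HbO2,298.0
670,Hb,2820.0
780,HbO2,710.0
780,Hb,1102.2
808,HbO2,866.0
808,Hb,723.5
850,HbO2,1058.0
850,Hb,691.3
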