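wavelength_nm,chromophore,epsilon_mm_per_mM
750,HbO2,0.1198
750,Hb,0.3226
850,HbO2,0.2436
850,Hb,0.1596
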