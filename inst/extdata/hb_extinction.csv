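wavelength_nm,eps_hbo2,eps_hb,units,source
650,0.368,3.75012,1/(mM*cm) base-10,literature compilation of hemoglobin molar extinction coefficients (Prahl tabulation)
930,1.214,0.69344,1/(mM*cm) base-10,literature compilation of hemoglobin molar extinction coefficients (Prahl tabulation)
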