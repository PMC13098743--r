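# Molar extinction coefficients of human oxy- (HbO2) and deoxy-hemoglobin (Hhb)
# Provenance: Gratzer/Kollias compilation as tabulated by S. Prahl (OMLC),
# converted from 1/(cm*M) to 1/(mM*mm) (factor 1e-4). The 785 nm row is
# linearly interpolated between the compilation's 760 and 800 nm rows.
# Columns: wavelength in nm; extinction coefficients in 1/(mM*mm).
wavelength_nm,eps_hbo2,eps_hhb
690,0.0276,0.205196
785,0.0730,0.1058
830,0.0974,0.069304
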