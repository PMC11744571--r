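# Molar extinction coefficients for oxy- and deoxyhemoglobin, 1/(mM*cm),
# compiled from W.B. Gratzer's tabulated hemoglobin spectra (via S. Prahl,
# Oregon Medical Laser Center) as commonly used in continuous-wave NIRS.
wavelength_nm,e_hbo,e_hbr
760,0.5862,1.5485
850,1.0580,0.6913
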