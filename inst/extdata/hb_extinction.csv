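# Hemoglobin extinction coefficients at the two oximeter wavelengths.
# Values are taken from the widely used compiled molar extinction
# spectra of human hemoglobin (log10 convention, cm^-1 per mol/L:
# O2Hb 650 / 974 and HHb 1311 / 693 at 770 / 830 nm) and converted to
# natural-log absorption per mm per mmol/L:
#   eps[mm^-1 mM^-1] = eps[cm^-1 M^-1] * ln(10) / 1e4
# Replaceable: any table in these units and columns is accepted by
# extinction_table(path).
wavelength_nm,eps_o2hb,eps_hhb
770,0.1496680,0.3018689
830,0.2242718,0.1595691
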