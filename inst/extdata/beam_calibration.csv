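# Calibrated pencil-beam configurations: range R80 (cm water), lateral FWHM (cm),
# neutrons produced per primary proton, neutrons detected in both tracking planes
# per primary proton.
label,energy_mev,range_r80_cm,fwhm_cm,yield_per_primary,detection_rate_per_primary
160MeV,160,17.7,1.0,0.08,1.4e-5
200MeV,200,25.9,1.0,0.13,2.5e-5
230MeV,230,32.9,1.0,0.18,3.2e-5
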