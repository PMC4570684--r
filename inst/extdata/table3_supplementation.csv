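supplement,concentration_mg_per_l,biomass_yield_g_g,q_s_mmol_gx_h,q_co2_mmol_gx_h,viability_fraction
none,0,0.49,-1.13,2.62,0.92
phloretic_acid,253,0.50,-1.12,2.58,0.91
cinnamic_acid,154,0.47,-1.18,,0.94
coumaric_acid,91,0.49,-1.14,2.67,0.93
resveratrol,6.3,0.49,-1.15,2.68,0.95
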