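strain,dilution_rate_1_per_h,feed_glucose_g_per_l,residual_glucose_mM,biomass_gdw_per_l,viability_fraction,resveratrol_uM,coumaric_uM,phloretic_uM,cinnamic_uM,q_o2_mmol_gx_h,q_co2_mmol_gx_h
FS09322,0.1,7.5,0.2,3.284,0.93,437,86,120,20,-3.09,3.18
CEN.PK113-7D,0.1,7.5,0.13,3.738,0.95,0,0,0,0,-2.61,2.65
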