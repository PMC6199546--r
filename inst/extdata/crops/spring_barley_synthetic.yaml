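# Synthetic spring barley parameter set (illustrative, not a site
# calibration).
name: spring_barley
planting_doy: 75
gdd_requirement: 1300
tbase: 0
kcb_stages: [0.30, 0.70, 1.05, 0.45]
stage_fractions: [0.20, 0.45, 0.80]
ke_soil: 0.35
wp_star: 15
hi: 0.45
root_depth: 0.9
depletion_p: 0.50
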