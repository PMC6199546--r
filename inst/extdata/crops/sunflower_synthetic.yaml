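# Synthetic sunflower parameter set (illustrative, not a site calibration).
name: sunflower
planting_doy: 100
gdd_requirement: 1350
tbase: 8
kcb_stages: [0.30, 0.75, 1.10, 0.55]
stage_fractions: [0.20, 0.45, 0.80]
ke_soil: 0.30
wp_star: 18
hi: 0.35
root_depth: 1.2
depletion_p: 0.45
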