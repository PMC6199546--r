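# Synthetic maize parameter set (illustrative values from standard
# crop-water-model literature ranges; not a site calibration).
name: maize
planting_doy: 110
gdd_requirement: 1450
tbase: 10
kcb_stages: [0.30, 0.80, 1.15, 0.70]
stage_fractions: [0.20, 0.45, 0.80]
ke_soil: 0.30
wp_star: 33
hi: 0.48
root_depth: 1.0
depletion_p: 0.55
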