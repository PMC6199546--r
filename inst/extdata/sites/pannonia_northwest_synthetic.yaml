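# Synthetic northwest-Pannonian site (role of a Gross-Enzersdorf-like
# station): drier, slightly cooler, Alpine-foreland influence.
climate:
  latitude: 48.20
  temp_mean: 10.8
  temp_amplitude: 10.5
  temp_phase_doy: 200
  temp_noise_sd: 2.2
  temp_autocorr: 0.6
  diurnal_range: 9.5
  p01: 0.24
  p11: 0.52
  gamma_shape: 0.8
  gamma_scale: 5.3
  sunshine_mean: 0.55
soil:
  fc: 0.30
  wp: 0.13
  sat: 0.44
  initial_fill: 0.7
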