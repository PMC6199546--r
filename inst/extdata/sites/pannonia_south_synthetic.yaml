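# Synthetic southern-Pannonian site (role of a Novi Sad-like station):
# moderate-continental, ~11.5 C annual mean, ~630 mm/yr precipitation.
climate:
  latitude: 45.33
  temp_mean: 11.5
  temp_amplitude: 11
  temp_phase_doy: 200
  temp_noise_sd: 2.0
  temp_autocorr: 0.6
  diurnal_range: 10
  p01: 0.25
  p11: 0.55
  gamma_shape: 0.8
  gamma_scale: 6.0
  sunshine_mean: 0.6
soil:
  fc: 0.33
  wp: 0.17
  sat: 0.46
  initial_fill: 0.8
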