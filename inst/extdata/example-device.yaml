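# Compact gas-exchange device: all lengths in mm.
geometry:
  rbc_width: 0.3
  rbc_height: 0.3
  window_length: 0.5
  window_width: 0.5
  pdms_pad_x: 0.5
  pdms_pad_y: 0.5
  pdms_pad_z: 0.5
  spincoat_thickness: 0.02
physics:
  mu_attenuation: 2      # 1/mm, optical attenuation of the suspension
  mean_velocity_rbc: 1   # mm/s
  mean_velocity_gas: 100 # mm/s
resolution:
  h_channel: 0.06
  h_axial: 0.15
  h_coarse: 0.5
  n_spincoat: 1
gas_mode: ideal-window
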