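# Demo run configuration: a small axial wire study imaged with a reduced
# wide-beam compounding sequence, plus the beating-LV cardiac stage.
array:
  n_elements: 32
  pitch_mm: 0.4
  width_mm: 0.3
  length_mm: 2.3
  fc_mhz: 3
  bandwidth: 0.55
sequence:
  strategy: widebeam
  n_angles: 9
  span_deg: 75
grid:
  depth_mm: 50
  width_mm: 20
  n_axial: 201
  n_lateral: 81
  z_min_mm: 10
phantom:
  kind: wires
  x_mm: [0, 0, 0]
  z_mm: [20, 35, 50]
cardiac:
  edv_ml: 120
  esv_ml: 50
  heart_rate_bpm: 75
  frame_rate_hz: 30
  n_cycles: 4
c_mps: 1540
fs_mhz: 20
noise_rms: 0
floor_db: -60
seed: 1
output_dir: echopatch-out
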