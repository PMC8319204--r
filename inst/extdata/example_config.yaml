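# Example configuration for the `mfi` CLI (see ?mfi_cli).
# Optics: 20x/NA 0.5 objective + 1.6x changer, 530-nm LED, 11-um pixels,
# four planes spanning 8.8 um.
optics:
  na: 0.5
  n: 1.0
  lambda: 0.53
  e_pixel: 11
  magnification: 32
  fov_px: 96
psf:
  w0: 2.1
  lambda: 0.53
diffusion:
  temperature: 295
  viscosity: 0.95e-3
  particle_radius: 250.0e-9
  frame_period: 0.002
beat:
  c0: 0.02
  c1: 0.05
  c2: 0.006
  f0: 25
n_frames: 20
n_beads: 3
grid:
  pitch: 8
  line_width: 0.8
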