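# Example desk-scale decomposition scenario (schema version 1).
# Units: time steps / duration / cadence in seconds, masses in ug C,
# rates in day^-1, D in voxel^2 day^-1.
schema: 1
geometry:
  kind: ball_packing
  dims: [24, 24, 24]
  n_balls: 8
  radius_range: [3, 5]
  seed: 11
initial:
  dom:
    total: 289.5
    placement: uniform
  mb:
    n_spots: 50
    cells: 5.2e+7
    mass_per_cell: 5.41e-8
    seed: 7
bio:
  rho: 0.2
  mu: 0.5
  beta: 0.55
  v_som: 0.01
  v_fom: 0.3
  v_dom: 9.6
  k_dom: 0.001
diffusion:
  D: 100950
  scheme: implicit
  dt: 300
transformation:
  mode: asynchronous
  dt: 300
duration: 7200
cadence: 3600
seed: 1
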