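lattice:
  nodes_per_axis:
  - 100
  - 100
  extent:
  - 0.0
  - 1.0
  adjacency: face
rate:
  lambda: 0.005
  alpha: 0.1
  beta: 3.0
  uv_mode: attenuated
  depth_axis: ~
  mode: neighbour
sampler:
  kind: fixed_tau
  c: 0.05
  tau_max: ~
  tau: ~
run:
  seeds: []
  stop_fraction: 0.5
  stop_count: ~
  max_steps: 1000000.0
  snapshots: []
study:
  'N': 1000
  f: 0.5
  spread_is: sd
  truncation: resample
  distributions:
    lambda:
    - 0.005
    - 0.001
    alpha:
    - 0.1
    - 0.02
    beta:
    - 3.0
    - 0.6
seed: 1
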