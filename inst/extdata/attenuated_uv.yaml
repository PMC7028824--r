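lattice:
  nodes_per_axis:
  - 32
  - 32
  - 32
  extent:
  - 0.0
  - 1.0
  adjacency: face
rate:
  lambda: 0.01
  alpha: 0.1
  beta: 1.0
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
study: ~
seed: 1
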