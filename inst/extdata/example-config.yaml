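# Example experiment configuration (all keys optional; unknown keys rejected).
preset: desk
architectures: [FF, LAT]
task:
  mode: VG
delays:
  vision: 9
  proprioception: 3
sensory:
  f_vision: 2
  f_prop: -4
  g: 200
  divisor: 20
decode:
  v: 2
encoding: bilinear
ea:
  generations: 1500
  p_mutate_agent: 0.4
  p_mutate_param: 0.5
  sigma_weights: 0.3
  sigma_bias: 3.0
  sigma_gain: 1.5
  elite_count: 1
  crossover: uniform
seed: 1
out_dir: parietoreach-results
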