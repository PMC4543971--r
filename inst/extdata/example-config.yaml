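# Example experiment configuration for the adaptivesis CLI.
# Model block mirrors model_params(); CLI flags override these values.
model:
  beta: 0.032
  psi_a: 0.65
  psi_b: 0.05
  p_a: 0.75
  mu: 0.002
  omega: 0.2
  n_nodes: 2000
  n_links: 20000
experiment: threshold-report
seed: 42
out_dir: results
window_factor: 10
t_max: 20000
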