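# Random-location ensemble for the wild-type mouse rod (one incisure).
# All lengths in micrometres, times in seconds.
preset: mouse
set: set1
n_trials: 300
seed: 1
t_end_s: 0.05
mesh:
  n_rho: 8
  n_theta: 12
  dt: 0.0005
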