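# Calibrated configuration of the modified two-armed bandit.
# These values are identical to the bandit_config() defaults; the methods
# vignette documents how they were chosen.
experiment: exp3
seed: 1
n_trials: 60
p_large_win: 0.6
p_small_win: 0.25
q_optimistic: 0.8
q_pessimistic: 0.05
preferences:
  large_win: 3.0
  small_win: 1.5
  "null": 0.0
  small_loss: -1.5
  large_loss: -3.0
initial_mass: 1.0
support_floor: 0.0025
policy_precision: 4.0
action_mode: sample
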