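# Analysis windows (ms after event onset, half-open [start, end)).
# Set per subject from the rise/fall of the population-averaged response.
subjects:
  P:
    start_cue: [200, 400]
    cost_cue: [150, 300]
    reward_cue: [140, 350]
    delivery: [225, 475]
    unpredictable_reward: [100, 300]
    airpuff: [30, 230]
  S:
    start_cue: [200, 400]
    cost_cue: [200, 400]
    reward_cue: [220, 420]
    delivery: [200, 450]
    unpredictable_reward: [150, 300]
    airpuff: [50, 200]
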