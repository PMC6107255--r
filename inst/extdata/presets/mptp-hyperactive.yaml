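# Hyperactive lesioned phenotype (version 1): intermittent high-intensity
# daytime tremor bursts on top of sleep disruption
name: mptp-hyperactive
activity: {}
effect:
  arousal_multiplier: 2
  sleep_bout_scale: 0.7
  l5_advance_min: 60
  hyperactive: true
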