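# Acute (1 month post-lesion) parkinsonian phenotype (version 1):
# halved daytime amplitude, tripled nocturnal arousal rate, halved sleep
# bouts, most-active period delayed 2 h, least-active period advanced 1 h
name: mptp-acute
activity: {}
effect:
  amplitude_scale: 0.5
  arousal_multiplier: 3
  sleep_bout_scale: 0.5
  m10_delay_min: 120
  l5_advance_min: 60
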