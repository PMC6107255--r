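# L-DOPA dose day on a lesioned animal (version 1): dose at 11:30 after
# 2.5 h of baseline recording; response rises 30 min post-dose, peaks at
# 70 min and lasts 4 h
name: ldopa-day
activity: {}
effect:
  amplitude_scale: 0.5
  arousal_multiplier: 3
  sleep_bout_scale: 0.5
dose:
  dose_time: "11:30"
  onset_latency_min: 30
  peak_latency_min: 70
  duration_min: 240
  peak_height_multiplier: 40
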