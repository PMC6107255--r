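# Vehicle dose day (version 1): identical to ldopa-day but with no pulse
# (peak height multiplier 1)
name: vehicle-day
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
  peak_height_multiplier: 1
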