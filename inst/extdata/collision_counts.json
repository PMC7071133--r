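{
  "description": "Published collision counts for holographic obstacle-avoidance trials, by foot role and hurdle, over the analysed repetitions (2-6) of the 12-participant cohort.",
  "obstacle_type": "holographic",
  "counts": {
    "lead_hurdle1": 39,
    "lead_hurdle2": 32,
    "trail_hurdle1": 143,
    "trail_hurdle2": 84
  }
}
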