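{
  "nstep": 50,
  "seed": 1,
  "default_p": 0.6,
  "mode": "exploration",
  "draw_nets": false,
  "stimuli": []
}
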