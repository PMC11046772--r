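{
  "nstep": 100,
  "seed": 1,
  "default_p": 0.6,
  "mode": "exploration",
  "draw_nets": false,
  "stimuli": [
    {
      "scope": "producer",
      "place": "LacI_protein",
      "n": 3,
      "r": 3
    }
  ]
}
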