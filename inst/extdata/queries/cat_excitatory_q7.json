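{
  "presynaptic": [
    {
      "channel": "synapsin",
      "size_um": [0.2, 0.2, 0.21]
    }
  ],
  "postsynaptic": [
    {
      "channel": "PSD-95",
      "size_um": [0.2, 0.2, 0.07]
    },
    {
      "channel": "NR1",
      "size_um": [0.2, 0.2, 0.21]
    }
  ],
  "k_pre": 3,
  "k_post": 1,
  "threshold": 0.6
}
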