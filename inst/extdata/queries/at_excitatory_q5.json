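{
  "presynaptic": [
    {
      "channel": "synapsin",
      "size_um": [0.2, 0.2, 0.14]
    },
    {
      "channel": "GluR2",
      "size_um": [0.2, 0.2, 0.07]
    }
  ],
  "postsynaptic": [
    {
      "channel": "PSD-95",
      "size_um": [0.2, 0.2, 0.07]
    }
  ],
  "k_pre": 3,
  "k_post": 1,
  "threshold": null
}
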