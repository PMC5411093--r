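{
  "height": 256,
  "width": 256,
  "n_slices": 20,
  "xy_nm": 100,
  "z_nm": 70,
  "channels": ["synapsin", "PSD-95"],
  "background": {
    "mu": 100,
    "sigma": 20
  },
  "populations": [
    {
      "name": "excitatory",
      "count": 50,
      "pre_channels": "synapsin",
      "post_channels": [
        "PSD-95"
      ],
      "snr": 5,
      "sigma_xy_um": 0.15,
      "slice_span": 3,
      "max_offset_um": 0.15
    }
  ],
  "distractors": {
    "single_channel": 25,
    "single_slice": 25
  },
  "min_separation_um": 0.6,
  "seed": 1337
}
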