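{
  "seed": 42,
  "n_acquisitions": 4,
  "simulate": { "frame_count": 240 },
  "counting": { "min_steps": 20 },
  "periodicity": { "kernel_width": 0.7, "bootstrap": 200 }
}
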