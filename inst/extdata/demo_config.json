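{
  "phantom": {
    "fov_mm": [8, 3],
    "pixel_size_um": 25,
    "frame_rate": 3,
    "noise_sigma_rel": 0.005,
    "duration_s": 25,
    "seeds": [
      {
        "nucleation_time": 4,
        "site": [4, 1.5],
        "law": "diffusion",
        "rate": 0.2
      }
    ]
  },
  "context_frames": [1, 2, 3, 4, 5, 6, 7, 8, 9],
  "fit_duration_s": 18,
  "seed": 5
}
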