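{
  "grating": {
    "period_nm": 400,
    "polymer_index": 1.46,
    "grating_depth_nm": 120,
    "grating_duty": 0.416,
    "grating_sidewall_deg": 85,
    "tio2_index": 2.4,
    "tio2_thickness_nm": 61,
    "tio2_duty": 0.5,
    "tio2_sidewall_deg": 82,
    "substrate_index": 1.52
  },
  "medium": { "superstrate_index": 1.333 },
  "instrument": {
    "wavelength_min_nm": 615,
    "wavelength_max_nm": 640,
    "wavelength_step_nm": 0.2,
    "fwhm_nm": 4,
    "noise_sd": 0.01,
    "pixel_pitch_um": 0.6,
    "frame_interval_s": 10
  },
  "seed": 1
}
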