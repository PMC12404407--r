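# Desk-scale duct-phantom experiment configuration (hollow vs fluid is
# chosen by the driver; `fill` here sets the default).
seed: 1
prestrain: 0.05
actuation_strain: 0.001
lambda0_nm: 1300
refr_index: 1.4
noise_floor: 1
pitch_um: [50, 50, 25]
layer_thickness_um: 500
layer_kpa: 16
fit_range_um: 100
snr_gate_db: 5
median_px: 3
enface_depth_um: 100
coupling_fwhm_um: 200
fill: hollow
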