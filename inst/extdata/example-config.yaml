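# Example calibration/threshold overrides for larvatrack::load_config().
# Unset keys keep the package defaults (66 um/px, 337 Hz recordings).
pixel_size_mm: 0.066
frame_rate_hz: 337
binarize_threshold: 25
min_eroded_change_px: 3
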