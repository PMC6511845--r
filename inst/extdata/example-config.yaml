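# Example end-to-end experiment configuration: motor on Rad51-filament
# ssDNA at the study scale. Any experiment_config() argument may appear;
# `acquisition` holds acquisition_params() overrides.
preset: rad51
n_events: 125
seed: 5
n_clusters: 9
bin_width: 10
n_boot: 1000
acquisition:
  n_frames: 150
  n_pixels: 150
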