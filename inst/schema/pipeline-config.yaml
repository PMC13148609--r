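# Declarative schema for the pipeline configuration. Every permitted key is
# listed; validate_config() rejects anything else and enforces types, enums
# and minima. "nullable: true" allows explicit nulls (meaning "unset").
input: {type: string, nullable: true}
output: {type: string, nullable: true}
output_format: {type: string, enum: [hdf5, tiff_stack, nifti, nrrd]}
memory_budget_bytes: {type: number, nullable: true, min: 1}
log_level: {type: string, enum: [debug, info, warning, error]}
seed: {type: integer}
raw_correction:
  type: section
  keys:
    flat_dark: {type: logical}
    bad_pixel: {type: logical}
    bad_pixel_k: {type: number, min: 0}
    threshold_median: {type: logical}
    threshold_median_threshold: {type: number, min: 0}
    threshold_median_window: {type: integer, min: 3}
    projection_stride: {type: integer, min: 1}
    tiling_method: {type: string, enum: [none, dead_reckoning, correlation]}
preprocess:
  type: section
  keys:
    phase_retrieval: {type: logical}
    gamma: {type: number, min: 0}
    pad_mode: {type: string, enum: [edge, reflect]}
    beam_hardening: {type: logical}
    c2: {type: number}
    bh_domain: {type: string, enum: [attenuation, intensity]}
reconstruction:
  type: section
  keys:
    cor_mode: {type: string, enum: [auto, manual, none]}
    cor_value: {type: number, nullable: true}
    rac_sort: {type: logical}
    rac_sort_filter_size: {type: integer, min: 3}
    rac_large: {type: logical}
    rac_large_snr: {type: number, min: 0}
    rac_large_filter_size: {type: integer, min: 1}
    filter: {type: string}
    cutoff_frac: {type: number, min: 0}
    circle_mask: {type: logical}
    circle_ratio: {type: number, min: 0}
    angle_min_deg: {type: number, nullable: true}
    angle_max_deg: {type: number, nullable: true}
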