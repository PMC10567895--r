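# Synthetic smartphone validation study: five phones, rear cameras for all,
# front cameras for four (one front camera omitted for lack of published
# specifications). Front cameras shoot a short-range distance set, back
# cameras reach 10 m. Two participants each miss one back camera.
study: smartphone
n_participants: 10
replicates: 2
front_distances_m: [0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.9, 1.1, 1.3]
back_distances_m: [0.3, 0.5, 0.7, 1, 2, 4, 6, 10]
priors:
  mean_pfl_mm: 30.7
  sd_pfl_mm: 1.2
pcs:
  mean_mm: 65
  sd_mm: 3.5
noise:
  landmark_jitter_sd_px: 0.5
  quantize: true
depth_model:
  depth_extent_mm: 100
threshold_pct: 1.0
model_variant: simple
seed: 1
phones:
  - name: iphone_5
    cameras:
      back: {focal_length_mm: 4.15, pixel_size_um: 1.4, megapixels: 8}
      front: {focal_length_mm: 2.18, pixel_size_um: 1.8, megapixels: 1.2}
  - name: iphone_xr
    cameras:
      back: {focal_length_mm: 4.25, pixel_size_um: 1.4, megapixels: 12}
  - name: moto_g9_plus
    cameras:
      back: {focal_length_mm: 5.53, pixel_size_um: 1.6, megapixels: 48}
      front: {focal_length_mm: 3.78, pixel_size_um: 2.0, megapixels: 20}
  - name: oppo_a57
    cameras:
      back: {focal_length_mm: 3.46, pixel_size_um: 1.1, megapixels: 13}
      front: {focal_length_mm: 3.57, pixel_size_um: 1.0, megapixels: 16}
  - name: samsung_galaxy_a31
    cameras:
      back: {focal_length_mm: 4.60, pixel_size_um: 1.6, megapixels: 64}
      front: {focal_length_mm: 3.80, pixel_size_um: 2.0, megapixels: 16}
dropouts:
  - {participant_id: 9, camera_name: oppo_a57_back}
  - {participant_id: 10, camera_name: iphone_xr_back}
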