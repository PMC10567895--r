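# Synthetic DSLR validation study: three full-frame bodies, five
# focal-length configurations each (three primes + the two end-range focal
# lengths of one variable zoom), six focus distances, frontal + profile
# views, duplicate exposures.
study: dslr
n_participants: 10
replicates: 2
distances_m: [1, 2, 3, 4, 6, 10]
priors:
  mean_pfl_mm: 30.7   # population mean palpebral fissure length (nominal adult value)
  sd_pfl_mm: 1.2
pcs:
  mean_mm: 65         # pupil-chord-to-stomion population distribution (nominal)
  sd_mm: 3.5
noise:
  landmark_jitter_sd_px: 0.5
  quantize: true
depth_model:
  depth_extent_mm: 100
threshold_pct: 1.0
model_variant: simple
seed: 1
bodies:
  - name: canon_6d
    pixel_size_um: 6.55
    sensor_width_mm: 35.8
    sensor_height_mm: 23.9
    megapixels: 20.2
    lenses:
      - {label: prime_50, focal_length_mm: 50}
      - {label: prime_85, focal_length_mm: 85}
      - {label: prime_100, focal_length_mm: 100}
      - {label: zoom_min, focal_length_mm: 24}
      - {label: zoom_max, focal_length_mm: 105}
  - name: canon_6d_mark_ii
    pixel_size_um: 5.67
    sensor_width_mm: 36.0
    sensor_height_mm: 24.0
    megapixels: 26.2
    lenses:
      - {label: prime_50, focal_length_mm: 50}
      - {label: prime_85, focal_length_mm: 85}
      - {label: prime_100, focal_length_mm: 100}
      - {label: zoom_min, focal_length_mm: 24}
      - {label: zoom_max, focal_length_mm: 105}
  - name: nikon_d780
    pixel_size_um: 5.90
    sensor_width_mm: 35.9
    sensor_height_mm: 23.9
    megapixels: 24.5
    lenses:
      - {label: prime_50, focal_length_mm: 50}
      - {label: prime_85, focal_length_mm: 85}
      - {label: prime_105, focal_length_mm: 105}
      - {label: zoom_min, focal_length_mm: 24}
      - {label: zoom_max, focal_length_mm: 120}
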