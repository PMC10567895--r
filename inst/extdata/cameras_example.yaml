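# Example flat camera configuration for read_camera_config(): one DSLR
# combination specified directly, one phone camera specified via its
# 35 mm-equivalent focal length and sensor diagonal.
cameras:
  - name: canon_6d_100mm
    focal_length_mm: 100
    pixel_size_um: 6.55
    sensor_diagonal_mm: 43.04
  - name: example_phone_back
    equivalent_focal_length_mm: 26
    sensor_diagonal_mm: 7.06
    pixel_size_um: 1.4
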