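# Example pipeline configuration for the urmc command-line front end.
# Any key omitted here falls back to the package default.
seed: 1
duration_s: 60
mean_rate_cps: 10000
ct_phase: 1.0          # deep-inspiration CT snapshot
signal_source: cod      # or "device" for the respiration-monitor arm
phantom:
  waveform:
    period: 4           # s
    si_amplitude: 20    # mm, diaphragm/liver superior-inferior travel
    ap_amplitude: 10    # mm, anterior chest/abdominal wall travel
    shape_exponent: 2
  lesions:
    - center: [35, 5, -15]
      diameter: 10      # mm
      uptake_ratio: 8
scanner:
  ring_radius: 300      # mm
  axial_half_length: 200
  tof_fwhm: 45          # mm positional TOF resolution
  tof_bin_width: 10
signal:
  bin_ms: 100
  dilation_mm: 50
gating:
  n_gates: 4
recon:
  n_iter: 3
  n_subsets: 8
  post_filter_mm: 2.5   # Gaussian sigma, ~6 mm FWHM
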