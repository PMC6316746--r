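# Example bioheat2d run configuration. Omitted keys inherit the defaults of
# default_run_config() (the published study parameter set). Temperatures may
# use a _K or _C suffix.
scenario:
  R1_mm: 60
  tumor_x_mm: 0
  tumor_y_mm: 10
  R2_mm: 3
solver:
  spacing_mm: 1.0
  tol: 1.0e-8
  max_iter: 100
  mode: steady
boundary:
  T_core_C: 36.35
  T_f_C: 19.85
sweep:
  position: [0, 10]
  R1_mm: [60, 70, 80]
  R2_mm: [2, 3, 4]
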