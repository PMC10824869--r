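# Demo pipeline configuration: base-case algorithm parameters with a
# widened moving window, standard thresholds and spacings.
params:
  moving_window_m: 60
seed: 7
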