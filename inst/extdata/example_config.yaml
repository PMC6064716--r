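# Example pipeline configuration. Any key omitted here keeps the package
# default (see ?load_config); unknown keys are rejected.
seed: 1
n_neurons: 30
frame_rate_hz: 7.8
spont_duration_s: 60
evoked_duration_s: 120
window_s: 10        # quietest-period length, seconds
threshold: 3        # epoch threshold, z-units
decay_tau_s: 1.5    # indicator decay for deconvolution, seconds
n_scrambles: 1000
n_resamples: 10000
alpha: 0.05
baseline_method: running_percentile
log_level: INFO
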