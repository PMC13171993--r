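# Example synthetic-participant configuration for gazejoint
# (see ?participant_model for field meanings; a moderately engaged viewer)
p_initiate: 0.9
p_rja: 0.7
p_request: 0.8
p_comment: 0.6
latency_mean_ms: 600
latency_sd_ms: 200
jitter_px: 4
dropout_rate: 0.02
sampling_hz: 300
seed: 42
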