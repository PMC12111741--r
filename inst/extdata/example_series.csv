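timestamp,series_id,temperature_c
2024-01-01T00:00:00,layer-mean-3,-3.25
2024-01-01T04:00:00,layer-mean-3,-3.1
2024-01-01T08:00:00,layer-mean-3,-2.8
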