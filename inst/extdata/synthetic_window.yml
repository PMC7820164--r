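# synthetic example plot window (meters)
x_min: 0.0
x_max: 120.0
y_min: 0.0
y_max: 100.0
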