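basicranial_cm	total_length_cm
83.1	449
100	542
125.5	683
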