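# units: uM
l_total_uM,signal
0.007,50.1
0.07,49.8
0.7,47.2
7,41.5
70,38.9
700,36.2
7000,31.0
40000,30.1
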