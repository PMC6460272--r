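time_min,cfu
0,176
15,116
30,86
45,38
60,22
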