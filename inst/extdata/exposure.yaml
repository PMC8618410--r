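# adult rice consumer, Spain
fir: 7.67
bw: 68.5
ef: 365
ed: 54
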