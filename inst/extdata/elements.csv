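element,rfd_mg_per_kg_d,csf_per_mg_per_kg_d,loq,loq_unit
Al,0.0004,,,
Cr,0.0030,0.5000,0.005,ug/g
As,0.0003,1.5000,0.002,ug/g
Cd,0.0010,0.3800,0.001,ug/g
Pb,0.0035,0.0085,0.002,ug/g
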