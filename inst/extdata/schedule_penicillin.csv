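label,ph,penicillin_mm,duration_s
buffer,7.4,0,30
pen_0.2mM,7.4,0.2,30
pen_0.5mM,7.4,0.5,30
pen_1mM,7.4,1,30
pen_2mM,7.4,2,30
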