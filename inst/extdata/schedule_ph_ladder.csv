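label,ph,penicillin_mm,duration_s
s01_pH7,7,0,30
s02_pH6,6,0,30
s03_pH5,5,0,30
s04_pH6,6,0,30
s05_pH7,7,0,30
s06_pH8,8,0,30
s07_pH9,9,0,30
s08_pH8,8,0,30
s09_pH7,7,0,30
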