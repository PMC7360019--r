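corpus,tag,count
mimic,B,23648
mimic,I,200272
mimic,O,91877
fv,B,43636
fv,I,336018
fv,O,35458
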