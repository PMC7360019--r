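corpus,type,count
mimic,period,12698
mimic,exclamation,4
mimic,question,24
mimic,semicolon,48
mimic,colon,4855
mimic,quotation,4
mimic,none,6018
fv,period,13619
fv,exclamation,19
fv,question,261
fv,semicolon,10
fv,colon,6180
fv,quotation,58
fv,none,23506
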