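"","N","S","V","F","Q"
"N",481587,130,403,1,7
"S",264,4123,6,0,0
"V",51,96,34157,7,0
"F",5,0,5,7,0
"Q",43,0,0,0,2017
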