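"","N","S","V","F","Q"
"N",481491,362,215,2,46
"S",438,3935,20,0,5
"V",172,116,33980,5,11
"F",1,0,2,8,6
"Q",71,0,5,0,1984
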