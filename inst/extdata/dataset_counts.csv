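dataset,aami_class,count
MIT-BIH,N,90386
MIT-BIH,S,3026
MIT-BIH,V,7708
MIT-BIH,F,803
MIT-BIH,Q,8043
S-Patch,N,5303245
S-Patch,S,27288
S-Patch,V,135013
S-Patch,F,0
S-Patch,Q,0
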