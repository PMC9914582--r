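group,tsqvc_printed,r_printed,letter
Egypt,1.07,0.35,a
Morocco,1.33,0.29,b
Greece,1.33,0.04,c
Spain,0.87,0.27,d
Nectar,1.05,0.08,e
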