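group,n,description
Egypt,7,Citrus honey from Egypt
Morocco,6,Citrus honey from Morocco
Greece,17,Citrus honey from Greece
Spain,8,Citrus honey from Spain
Nectar,6,Other nectar honeys from Greece
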