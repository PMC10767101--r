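class,count
incisor,91
canine,54
premolar,212
molar,355
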