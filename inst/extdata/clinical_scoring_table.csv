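category,level,both,a_only,c_only
lobe,frontal,245,42,80
lobe,temporal,181,34,60
lobe,parietal,97,20,22
lobe,occipital,5,2,6
type,intracortical,393,81,121
type,juxtacortical,103,10,36
type,mixed,32,7,11
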