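label	numerator	denominator	digits
heart_enhancer_overlap	240	292	1
nonheart_enhancer_overlap	476	1305	1
promoter_involving_interactions	4361	14712	2
dynamic_interactions	145	2302	1
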