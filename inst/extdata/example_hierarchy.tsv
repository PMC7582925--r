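id	name	parent
brain	brain	NA
cerebrum	cerebrum	brain
brainstem	brainstem	brain
cerebellum	cerebellum	brain
frontal cortex	frontal cortex	cerebrum
hippocampus	hippocampus	cerebrum
CA1	CA1 field	hippocampus
pons	pons	brainstem
medulla	medulla	brainstem
cerebellar cortex	cerebellar cortex	cerebellum
white matter tracts	white matter tracts	brain
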