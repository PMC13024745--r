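group,count
C6H3_benzene_trisub,1
C6H4_phenylene,1
F,1
ring_methylidene_cyclopentadiene,1
CH3,2
CH2,1
COOH,1
SO_sulfoxide,1
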