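group,count
CH3,1
NH,1
CH2,2
CH_OH,4
OH,1
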