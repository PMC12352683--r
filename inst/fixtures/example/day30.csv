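"day","taxon","value"
30,"E",0.382629539471734
30,"B",0.214362062354687
30,"BC",0.223126963699208
30,"C",0.16826683179457
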