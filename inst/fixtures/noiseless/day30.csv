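"day","taxon","value"
30,"E",0.429139586145343
30,"B",0.157227261805291
30,"BC",0.215774451729321
30,"C",0.197858700320045
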