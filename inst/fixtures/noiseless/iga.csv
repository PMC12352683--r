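"taxon","value"
"E",0.288628949408165
"B",-0.220392807471697
"BC",-0.12976850293522
"C",-0.12976850293522
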