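"taxon","value"
"E",0.324265225480762
"B",-0.160357214802873
"BC",-0.118617093347801
"C",-0.124302940939004
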