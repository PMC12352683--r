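"day","taxon","value"
721,"E",0.290755144081246
721,"B",0.163271571208187
721,"BC",0.306016187446937
721,"C",0.270028815470233
728,"E",0.259907963306041
728,"B",0.16886920074879
728,"BC",0.293402622928381
728,"C",0.285481222035221
735,"E",0.273145111874624
735,"B",0.167650384015814
735,"BC",0.319976187871541
735,"C",0.27583199542772
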