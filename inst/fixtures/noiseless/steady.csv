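"day","taxon","value"
721,"E",0.337871571081365
721,"B",0.143121656355049
721,"BC",0.266792297446676
721,"C",0.252214475116911
728,"E",0.337871571081456
728,"B",0.143121656355017
728,"BC",0.266792297446646
728,"C",0.252214475116882
735,"E",0.337871571081367
735,"B",0.143121656355048
735,"BC",0.266792297446675
735,"C",0.25221447511691
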