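"day","taxon","value"
3,"E",0.838441996129823
3,"B",0.150269269198813
3,"BC",0
3,"C",0
24,"E",0.546785603090783
24,"B",0.458101153636382
24,"BC",0.0264721129242404
24,"C",0.0124983557988943
45,"E",0.553546303952955
45,"B",0.425456825419477
45,"BC",0
45,"C",0
66,"E",0.532497273794751
66,"B",0.431625553354209
66,"BC",0
66,"C",0.000246539353589357
87,"E",0.561354310296613
87,"B",0.45194173184666
87,"BC",0
87,"C",0
108,"E",0.552987553025944
108,"B",0.43304493067519
108,"BC",0
108,"C",0.00705114998897632
129,"E",0.568381250039297
129,"B",0.433225337614144
129,"BC",0
129,"C",0
150,"E",0.56259361789723
150,"B",0.413313473938468
150,"BC",0
150,"C",0
171,"E",0.401481588227174
171,"B",0.291813013040067
171,"BC",0.153192012356293
171,"C",0.127830685696851
192,"B",0.304761038238895
192,"BC",0.212010666896662
192,"C",0.127159061455332
213,"B",0.291064104568661
213,"BC",0.157106593946024
213,"C",0.149975359674376
234,"B",0.307911751984741
234,"BC",0.179019501221983
234,"C",0.175088184789945
255,"B",0.27742434917493
255,"BC",0.157565404617511
255,"C",0.18049525559309
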