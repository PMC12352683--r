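"day","taxon","value"
3,"E",0.869331846094566
3,"B",0.130668153905434
3,"BC",0
3,"C",0
24,"E",0.575414723244636
24,"B",0.424585276755364
24,"BC",0
24,"C",0
45,"E",0.596369314811138
45,"B",0.403630685188861
45,"BC",0
45,"C",0
66,"E",0.601806137434103
66,"B",0.398193862565897
66,"BC",0
66,"C",0
87,"E",0.603300042222601
87,"B",0.396699957777399
87,"BC",0
87,"C",0
108,"E",0.603768812726132
108,"B",0.396231187273868
108,"BC",0
108,"C",0
129,"E",0.60392608775392
129,"B",0.39607391224608
129,"BC",0
129,"C",0
150,"E",0.603980290198053
150,"B",0.396019709801947
150,"BC",0
150,"C",0
171,"E",0.432302303091023
171,"B",0.303282247250543
171,"BC",0.15800013555638
171,"C",0.106415314102053
192,"B",0.289040725750483
192,"BC",0.168359020218552
192,"C",0.128449509283277
213,"B",0.279399760752916
213,"BC",0.176971318425132
213,"C",0.138421133197699
234,"B",0.27207025340134
234,"BC",0.183523988986283
234,"C",0.145990697218368
255,"B",0.266734763469684
255,"BC",0.188294137048512
255,"C",0.151494190066396
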