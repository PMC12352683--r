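"day","density"
0,18242552380.6356
7,24048908305.0889
14,31002551887.2388
21,38936076605.0778
28,47502081252.106
35,56217650088.5798
42,64565630622.5795
49,72111517802.2863
56,78583498304.2559
63,83889105042.3415
70,88079707797.7882
77,91293422755.9729
84,93702664394.3004
91,95478252651.6712
98,96770453530.1549
105,97702263008.9974
112,98369750062.8559
119,98845624751.6078
126,99183742884.684
133,99423403444.1075
140,99592986228.4104
147,99712837084.4299
154,99797467961.095
161,99857192671.1577
168,99899322917.9914
175,99929032960.09
182,99949979889.2921
189,99964746216.2129
196,99975154491.8161
203,99982490381.5885
210,99987660542.4014
217,99991304214.3232
224,99993872026.0383
231,99995681611.5868
238,99996956844.3099
245,99997855505.1579
252,99998488790.4559
259,99998935063.8806
266,99999249549.8403
273,99999471165.5385
280,99999627336.0716
287,99999737387.8792
294,99999814940.2227
301,99999869590.5078
308,99999908101.9487
315,99999935240.5202
322,99999954364.7571
329,99999967841.3836
336,99999977338.2039
343,99999984030.5011
350,99999988746.4838
357,99999992069.7809
364,99999994411.6689
371,99999996061.9696
378,99999997224.9168
385,99999998044.4319
392,99999998621.9345
399,99999999028.8936
406,99999999315.6729
413,99999999517.7628
420,99999999660.1732
427,99999999760.5281
434,99999999831.247
441,99999999881.0818
448,99999999916.1997
455,99999999940.947
462,99999999958.386
469,99999999970.6751
476,99999999979.3351
483,99999999985.4377
490,99999999989.7381
497,99999999992.7686
504,99999999994.9041
511,99999999996.409
518,99999999997.4695
525,99999999998.2168
532,99999999998.7434
539,99999999999.1145
546,99999999999.376
553,99999999999.5603
560,99999999999.6901
567,99999999999.7816
574,99999999999.8461
581,99999999999.8916
588,99999999999.9236
595,99999999999.9462
602,99999999999.9621
609,99999999999.9733
616,99999999999.9812
623,99999999999.9867
630,99999999999.9906
637,99999999999.9934
644,99999999999.9954
651,99999999999.9967
658,99999999999.9977
665,99999999999.9984
672,99999999999.9988
679,99999999999.9992
686,99999999999.9994
693,99999999999.9996
700,99999999999.9997
707,99999999999.9998
714,99999999999.9999
721,99999999999.9999
728,99999999999.9999
735,1e+11
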