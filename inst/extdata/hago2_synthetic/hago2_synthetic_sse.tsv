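lobe	kind	start	end
N	H	1	20
N	S	31	36
N	H	45	60
N	S	69	74
N	H	83	100
N	S	109	114
N	S	121	126
N	S	133	138
N	S	145	150
N	S	157	168
N	S	175	180
N	S	185	190
N	S	191	196
N	S	207	212
N	S	213	218
N	H	231	245
N	H	256	270
N	S	281	286
N	H	295	310
N	S	321	326
N	S	335	340
N	S	349	356
N	H	357	372
N	S	381	386
N	H	395	410
N	S	421	426
C	H	446	460
C	S	466	470
C	H	476	487
C	S	492	496
C	H	501	510
C	S	515	519
C	H	524	533
C	H	538	550
C	S	555	558
C	S	563	566
C	S	570	571
C	S	580	583
C	H	586	588
C	S	591	599
C	S	604	610
C	S	611	617
C	H	626	640
C	S	649	653
C	S	661	668
C	H	675	695
C	S	702	708
C	S	715	717
C	H	737	746
C	S	749	751
C	S	766	770
C	S	779	790
C	S	799	802
C	H	803	820
C	S	829	834
C	H	841	855
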