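domain	start	end
N	1	160
L1	161	226
PAZ	227	350
L2	351	445
MID	446	580
PIWI	581	862
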