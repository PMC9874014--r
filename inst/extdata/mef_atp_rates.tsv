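condition	atp_arbitrary_dmem	atp_arbitrary_rw	atp_measured_pmol_ng_day	net_synthesis_rw_day	net_synthesis_measured_day
WT	239	183	187	0.135	0.326
G12D	451	399	269	1.102	0.979
G12V	256	297	268	0.673	0.651
Q61L	383	329	254	0.791	0.741
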