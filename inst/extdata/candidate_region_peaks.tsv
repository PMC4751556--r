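peak	chrom	peak_pos	ci_start	ci_end	genes	selection_type
1	X	1252000	1237000	1339000	CG11417,CG11418,CG11448,CG12773,CG14770,CG14773,CG3056,CG32813,CG3719,SNF1A,futsch,png	3
2	X	13237000	13211000	13250000	CG15747,IP3K2,Jafrac1,RpS15Aa	2
3	2L	1515000	1476000	1559000	CG14351,CG18131,CG18132,CG31661,CG31926,CG31928,CG33128,CG7420,Or22a,Or22b,halo	2
4	2L	13159000	13316000	13438000	CG10859,CG16826,CG16848,CG16956,CG16957,CG16970,CG31855,CG6523,CG6565,CG7099,CG7110,CG9293,CG9302,CG9305,CG9306,CG9377,CG9395,Nnp-1,RpL24,Tap42,Tehao,Vm34Ca,beta'Cop,loqs	1
7	3R	9109000	9061000	9192000	Ace,CG11686,CG15887,CG15888,CG32473,CG8449,CG8630,CG8773,CG8774,CG8784,CG8790,CG8795,CheA87a,Lip3,Osi22,Ravus,Su(var)3-7,mthl12,poly,wntD	2
8	3R	9608000	9601000	9638000	CG42375,CG9286,CG9288,CG9297,Cht5,Dip-B,tRNA:CR31331,tRNA:CR31588,tal-1A,tal-2A,tal-3A,tal-AA	2
9	3R	25260000	25245000	25271000	Ptp99A	2
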