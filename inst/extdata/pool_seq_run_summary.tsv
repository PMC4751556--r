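generation	condition	replicate	read_length	read_number	mapped_read_number	mapped_pct	mean_depth
0	base	1	100	386775696	361193875	93.39	214
22	LD	1	100	266855274	254924548	95.53	151
22	LD	2	100	283632172	272484316	96.07	161
22	LD	3	100	269666516	259954602	96.40	154
22	DD	1	100	271880364	258818394	95.20	153
22	DD	2	100	265563806	254379699	95.79	151
22	DD	3	100	274437396	262753186	95.74	156
49	LD	1	100	351537438	329248183	93.66	195
49	LD	2	100	386629584	362194949	93.68	215
49	LD	3	100	269858658	243812205	90.35	144
49	DD	1	100	418334430	386895826	92.48	229
49	DD	2	100	345057530	317678449	92.07	188
49	DD	3	100	379634634	354977577	93.51	210
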