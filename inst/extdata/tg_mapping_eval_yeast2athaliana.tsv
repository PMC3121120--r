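set	mapped_tgs	tp	fp	tn	fn
TGbl	2252	1717	535	9625	23474
TGbs	35181	25180	10001	159	11
TGblbs	2252	1717	535	9625	23474
TGpr	25259	24973	286	49	218
TGgalf	25388	25077	311	24	114
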