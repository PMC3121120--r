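set	mapped_tfs	mapped_tgs	links_mapped	links_analyzed	verified	strong_3x	strong_2x	weak	unsupported
TFsf-TGblbs	118	2252	43423	3056	2090	2109	58	103	786
TFf-TGblbs	434	2252	480524	8621	2628	2375	344	215	5687
TFsf-TGbs	118	35181	536154	6085	2995	2968	30	100	2987
TFsf-TGpr	118	25259	274400	34529	2343	2323	26	66	2050
TFf-TGpr	434	25259	3182551	236585	93287	101224	12737	19037	87983
TFf-TGgalf	434	25388	242030	25227	3727	2012	1715	503	150
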