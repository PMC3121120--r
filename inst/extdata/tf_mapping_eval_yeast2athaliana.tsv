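set	mapped_links	mapped_tfs	tp	fp	tn	fn
TFbl	1344	767	400	367	33062	1522
TFf	903	434	328	106	33323	1594
TFsf	212	118	91	27	33402	1831
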