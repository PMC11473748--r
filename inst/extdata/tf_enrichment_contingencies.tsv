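# 2x2 contingency counts behind the TF binding-site enrichment statistics of
# the guard-cell ABA study this package models. Of the 170 B. napus
# transcription factors whose binding sites are enriched upstream of
# up-regulated genes, 29 are themselves up-regulated (vs 1,944 up-regulated
# genes among the 101,040 annotated) and 23 belong to the ABA signaling
# pathway (vs 435 pathway members among the 101,040 annotated).
comparison	k	set_size	universe_hits	universe
tf_set_vs_upregulated	29	170	1944	101040
tf_set_vs_aba_pathway	23	170	435	101040
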