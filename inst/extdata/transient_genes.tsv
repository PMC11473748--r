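# Genes with transient regulation in the first hour of ABA treatment in
# B. napus guard cells: significant at 15 min but not at 60 min (FDR 0.05).
# Curated reference table from the guard-cell ABA time-course experiment
# this package models.
pattern	bnapus_id	athaliana_id	common_name	fdr15	fdr60
only_down_15	BnaA05g12320D	AT2G30040	MAPKKK14	0.00986	0.195
only_down_15	BnaA08g02360D	AT1G49850	NA	0.03198	0.683
only_down_15	BnaA09g11950D	AT1G64090	RTNLB3	0.02868	0.071
only_down_15	BnaA09g27780D	AT1G27730	STZ	0.00735	0.814
only_down_15	BnaC03g39060D	AT3G15353	ATMT3	0.02381	0.718
only_down_15	BnaC05g21480D	AT1G27730	STZ	0.00029	0.889
only_down_15	BnaC06g40000D	AT1G79660	NA	0.02328	0.485
only_up_15	BnaAnng27240D	AT4G19230	CYP707A1	0.00192	0.074
only_up_15	BnaC01g11650D	AT4G19230	CYP707A1	0.01032	0.536
only_up_15	BnaC05g31990D	NA	NA	0.01387	0.088
only_up_15	BnaC06g32150D	AT1G71010	FAB1C	0.01980	0.513
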