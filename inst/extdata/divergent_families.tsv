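# B. napus ortholog families whose members show the most divergent 60-min
# log2 fold changes under ABA (family SD of member LFCs > 1.6), with the
# printed member fold changes and adjusted p-values ("NA" = filtered).
# Curated reference table from the guard-cell ABA time-course experiment
# this package models.
group	athaliana_id	bnapus_id	common_name	lfc60	adj_p
1	AT4G21060	BnaA01g10960D	AtGALT2	-0.2087579	0.1760
1	AT4G21060	BnaC01g12450D	AtGALT2	-0.2131616	0.32058
1	AT4G21060	BnaC07g36550D	AtGALT2	3.3005180	<2e-16
2	AT4G27410	BnaA01g16400D	ANAC072	3.6033603	<2e-16
2	AT4G27410	BnaA03g48570D	ANAC072	3.3041495	<2e-16
2	AT4G27410	BnaC01g19550D	ANAC072	0.1300110	0.70897
2	AT4G27410	BnaC07g40860D	ANAC072	3.1791690	<2e-16
3	AT3G15670	BnaA01g28600D	NA	0.6381671	NA
3	AT3G15670	BnaA05g23860D	NA	4.3448604	<2.22e-16
3	AT3G15670	BnaC01g35900D	NA	0.0754009	NA
3	AT3G15670	BnaC03g39230D	NA	0.0512065	NA
3	AT3G15670	BnaC05g37670D	NA	4.0675792	<2.22e-16
4	AT3G02480	BnaA01g32930D	NA	-0.0509738	NA
4	AT3G02480	BnaA03g27910D	NA	4.4150238	<2.22e-16
4	AT3G02480	BnaC03g32950D	NA	2.2319576	4.1865e-12
5	AT3G17520	BnaA03g34560D	NA	0.4042299	NA
5	AT3G17520	BnaAnng35040D	NA	5.0627122	<2.22e-16
5	AT3G17520	BnaC03g40050D	NA	1.4258471	2.1121e-05
5	AT3G17520	BnaC05g35990D	NA	3.5844242	<2.22e-16
6	AT4G34020	BnaA03g50810D	AtDJ1C	3.8242444	<2e-16
6	AT4G34020	BnaAnng26560D	AtDJ1C	0.2359967	0.47863
6	AT4G34020	BnaC01g04310D	AtDJ1C	0.3422487	0.090944
6	AT4G34020	BnaC01g04320D	AtDJ1C	-0.0557400	NA
7	AT2G47770	BnaA04g29550D	ATTSPO	2.7599247	<2.22e-16
7	AT2G47770	BnaA05g00220D	ATTSPO	1.9034236	7.381e-16
7	AT2G47770	BnaC04g00110D	ATTSPO	0.1170079	0.58354
7	AT2G47770	BnaC04g51120D	ATTSPO	4.2157486	<2.22e-16
8	AT1G69260	BnaA07g24330D	AFP1	3.7297320	<2.22e-16
8	AT1G69260	BnaA07g27800D	AFP1	0.6839890	NA
8	AT1G69260	BnaC06g25430D	AFP1	4.1553036	<2.22e-16
8	AT1G69260	BnaC06g30430D	AFP1	0.0644924	NA
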