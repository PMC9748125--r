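chrom	pos	allele1	f_a	f_u	allele2	gene	cohort
ECA7	41381993	A	0.2715	0.4980	G	NTM	global
ECA18	48638568	A	0.1873	0.3956	G	G6PC2	global
ECA22	1289141	T	0.0414	0.1714	C	SYNDIG1	global
ECA18	49159216	T	0.4678	0.6741	C	FASTKD1	global
ECA18	49230205	A	0.5418	0.7117	G	PPIG	global
ECA4	51109357	G	0.6616	0.8117	A	HDAC9	global
ECA22	23460297	A	0.3783	0.2541	T	MYLK2	global
ECA5	52312504	G	0.1184	0.2146	C	SLC16A1	global
ECA24	3586665	G	0.1816	0.2831	A	KTN1	global
ECA15	83175651	C	0.0861	0.1586	A	NA	global
ECA2	101601341	A	0.3783	0.4859	G	NA	global
ECA28	34013061	G	0.3132	0.2329	C	NA	global
ECA2	66547160	G	0.1351	0.2033	A	NA	global
ECA27	38633488	T	0.0947	0.1209	C	NA	global
ECA16	52850203	G	0.6556	0.4625	A	GLB1	mongolian
ECA15	12036913	C	0.1413	0.2563	T	NA	mongolian
ECA16	72765824	G	0.1957	0.1281	A	NA	mongolian
ECA4	55899514	G	0.6667	0.4213	C	NA	mongolian
ECA7	64406448	A	0.1304	0.1125	G	NA	mongolian
ECA26	16940454	A	0.1000	0.0917	G	NA	mongolian
ECA21	3979432	T	0.0978	0.0924	C	NA	mongolian
ECA5	49201314	A	0.4222	0.4174	C	NA	mongolian
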