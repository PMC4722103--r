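run	raw_gb	raw_reads	qc_pipeline_gb	qc_pipeline_reads	qc_ngs_gb	qc_ngs_reads
1	18.46	35371138	6.50	23505862	6.43	23151200
2	10.82	20766464	7.59	17580296	7.58	17507722
3	3.97	7974858	2.53	6239280	2.52	6202911
4	8.56	17264916	5.96	14037596	5.95	13964065
5	6.97	15136922	5.61	12272954	5.60	12216490
6	0.90	1833418	0.59	1407000	0.58	1387258
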