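domain	sample_id	cloud_type	fraction	reads	observed	ace	shannon_h	gini
prokaryote	cloud1	Polluted	DNA	496197	20432	20954	9.1	0.74
prokaryote	cloud1	Polluted	RNA	59449	3428	4710	6.3	0.98
prokaryote	cloud2	Continental	DNA	115515	7793	10802	7.2	0.95
prokaryote	cloud2	Continental	RNA	81196	5622	6468	7.3	0.95
prokaryote	cloud3	Marine	DNA	150017	8970	11148	7.4	0.94
eukaryote	cloud1	Polluted	DNA	18562	2061	2461	6.58	0.75
eukaryote	cloud1	Polluted	RNA	12831	1527	1845	6.28	0.81
eukaryote	cloud2	Continental	DNA	13978	1901	2400	6.48	0.77
eukaryote	cloud2	Continental	RNA	24673	1692	1834	6.32	0.81
eukaryote	cloud3	Marine	DNA	15662	1877	2439	6.26	0.79
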