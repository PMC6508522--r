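gene_id	count_sh	count_yk	rnaseq	qpcr
Thhalv10021382m.g	4	87	4.4	12.5
Thhalv10000662m.g	46	429	3.2	4.4
Thhalv10015083m.g	34265	2494	-3.8	-5661.5
Thhalv10011087m.g	1445	327	-2.1	n.s.
XLOC_024729	237	25	-3.2	-2.0
Thhalv10015718m.g	0	48	Absent in SH	Not detected in SH
Thhalv10029390m.g	0	83	Absent in SH	Not detected in SH
Thhalv10021522m.g	1	244	7.9	144.9
Thhalv10014718m.g	1	86	6.4	11.8
Thhalv10002969m.g	61	0	Absent in YK	-58.3
Thhalv10009345m.g	58	0	Absent in YK	Not detected in YK
Thhalv10014264m.g	53	0	Absent in YK	Not detected in YK
Thhalv10000285m.g	179	0	Absent in YK	Not detected in YK
Thhalv10022943m.g	148	0	Absent in YK	Not detected in YK
Thhalv10023491m.g	47	0	Absent in YK	Not detected in YK
Thhalv10018393m.g	70	1	-6.1	1.7
XLOC_005768	0	99	Absent in SH	Not detected in SH
XLOC_017575	50	0	Absent in YK	Not detected in YK
XLOC_003055	55	0	Absent in YK	Not detected in YK
XLOC_024727	53	0	Absent in YK	Not detected in YK
XLOC_003052	318	1	-8.3	-257.7
XLOC_008740	135	3	-5.5	Not detected in YK
XLOC_020731	76	0	Absent in YK	Not detected in YK
XLOC_017573	246	0	Absent in YK	Not detected in YK
XLOC_015175	75	0	Absent in YK	Not detected in YK
Thhalv10022994m.g	0	46	Absent in SH	Not tested
Thhalv10022932m.g	74	1	-6.2	Not tested
Thhalv10014933m.g	295	32	-3.2	Not tested
Thhalv10019398m.g	6	217	5.2	Not tested
Thhalv10029246m.g	0	47	Absent in SH	Not tested
XLOC_004723	187	16	-3.5	Not tested
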