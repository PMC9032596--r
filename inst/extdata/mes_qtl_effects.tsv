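qtl	bin	chromosome	environment	pos_cM	marker_interval	lod	a	d	pve
qMES1-1	1.09	1	3cm	110.9	umc2047-bnlg1597	3.10	0.25	0.03	2.89
qMES1-1	1.09	1	15cm	110.8	umc2047-bnlg1597	8.84	-0.75	-0.11	8.34
qMES1-1	1.09	1	20cm	110.8	umc2047-bnlg1597	10.43	-0.91	-0.15	10.01
qMES1-2	1.10	1	15cm	145.2	umc1534-umc2223	13.96	-1.17	0.10	13.12
qMES3-1	3.04	3	15cm	55.3	umc1527-umc2261	7.10	-1.88	-0.21	11.60
qMES3-1	3.04	3	20cm	56.1	umc1527-umc2261	4.77	-1.03	-1.20	4.94
qMES4-1	4.06-4.07	4	3cm	88.1	umc1869-umc1775	4.08	-0.34	-0.02	3.81
qMES4-1	4.06-4.07	4	15cm	88.0	umc1869-umc1775	10.02	-0.83	-0.09	9.46
qMES4-1	4.06-4.07	4	20cm	88.2	umc1869-umc1775	14.84	-1.25	-0.18	13.97
qMES4-2	4.05-4.08	4	15cm	119.1	umc1612-umc1313	4.44	-1.10	0.08	6.98
qMES4-2	4.05-4.08	4	20cm	119.4	umc1612-umc1313	4.61	0.17	0.10	8.42
qMES6-1	6.01	6	3cm	14.3	umc2311-umc2196	9.30	-1.01	-1.51	8.11
qMES6-1	6.01	6	15cm	14.3	umc2311-umc2196	5.81	-0.61	0.97	5.06
qMES6-1	6.01	6	20cm	14.3	umc2311-umc2196	11.45	-1.14	-1.43	10.03
qMES7-1	7.02	7	3cm	67.0	umc1585-umc2526	3.08	-0.80	-0.03	4.93
qMES7-1	7.02	7	15cm	66.9	umc1585-umc2526	2.29	-0.61	0.08	3.67
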