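gene	coexpr_neighbors	other_neighbors	coexpr_total	network_total	ratio	p	fdr
CCNE1	12	87	392	17381	0.121212	2.31E-06	0.000839
CDT1	11	60	392	17381	0.15493	5.08E-07	0.000188
MCM6	15	108	392	17381	0.121951	1.16E-07	4.39E-05
ORC6	7	26	392	17381	0.212121	7.24E-06	0.002622
CDK1	33	203	392	17381	0.139831	4.17E-17	1.63E-14
MCM10	10	55	392	17381	0.153846	1.80E-06	0.000657
FOXM1	13	72	392	17381	0.152941	5.45E-08	2.08E-05
DSN1	8	44	392	17381	0.153846	1.97E-05	0.007069
CENPE	7	33	392	17381	0.175	2.76E-05	0.00985
BUB1B	16	88	392	17381	0.153846	1.44E-09	5.56E-07
CENPH	8	28	392	17381	0.222222	1.08E-06	0.000399
NDC80	16	68	392	17381	0.190476	5.22E-11	2.03E-08
RMI1	6	17	392	17381	0.26087	9.24E-06	0.003334
CCNA2	16	119	392	17381	0.118519	6.61E-08	2.51E-05
POLA1	12	42	392	17381	0.222222	2.14E-09	8.25E-07
MCM3	19	160	392	17381	0.106145	2.40E-08	9.18E-06
RAD51	14	112	392	17381	0.111111	9.75E-07	0.00036
FBXO5	9	29	392	17381	0.236842	1.26E-07	4.73E-05
CHEK1	17	99	392	17381	0.146552	9.53E-10	3.70E-07
CENPA	14	102	392	17381	0.12069	3.51E-07	0.000131
CDC7	11	24	392	17381	0.314286	1.71E-10	6.67E-08
CENPN	7	19	392	17381	0.269231	1.28E-06	0.000469
CCNE2	7	29	392	17381	0.194444	1.34E-05	0.004806
E2F1	16	122	392	17381	0.115942	9.02E-08	3.42E-05
PRC1	11	33	392	17381	0.25	2.63E-09	1.01E-06
TIPIN	5	11	392	17381	0.3125	2.02E-05	0.007246
CDC6	18	50	392	17381	0.264706	7.03E-15	2.75E-12
NUF2	10	34	392	17381	0.227273	3.80E-08	1.45E-05
CDC45	10	39	392	17381	0.204082	1.14E-07	4.31E-05
DBF4	8	21	392	17381	0.275862	1.77E-07	6.61E-05
CENPK	7	8	392	17381	0.466667	1.55E-08	5.95E-06
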