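atom1	atom2	order	pi1	pi2	mean	sigma	count
C	C	1	0	0	1.530	0.016	240
C	C	1	0	1	1.507	0.018	180
C	C	1	1	1	1.460	0.020	160
C	C	2	1	1	1.335	0.014	150
C	C	2	1	2	1.308	0.014	40
C	C	3	2	2	1.203	0.012	60
C	N	1	0	0	1.469	0.016	200
C	N	1	1	0	1.340	0.020	160
C	N	1	1	1	1.355	0.022	80
C	N	2	1	1	1.279	0.014	120
C	N	3	2	2	1.136	0.011	70
C	O	1	0	0	1.426	0.016	220
C	O	1	1	0	1.300	0.035	180
C	O	2	1	1	1.215	0.012	200
C	S	1	0	0	1.815	0.020	90
C	S	1	1	0	1.755	0.030	60
C	S	2	1	1	1.670	0.016	40
C	F	1	0	0	1.350	0.015	110
C	Cl	1	0	0	1.775	0.016	100
C	Br	1	0	0	1.935	0.018	60
C	I	1	0	0	2.140	0.022	40
N	N	1	0	0	1.450	0.018	70
N	N	1	1	1	1.330	0.020	50
N	N	2	1	1	1.245	0.012	60
N	N	3	2	2	1.125	0.010	30
N	O	1	0	0	1.405	0.018	60
N	O	1	1	0	1.235	0.020	90
N	O	2	1	1	1.210	0.012	100
O	O	1	0	0	1.470	0.015	30
O	O	2	1	1	1.207	0.010	10
O	P	1	0	0	1.600	0.022	80
O	P	2	1	1	1.500	0.018	70
O	S	1	0	0	1.560	0.035	60
O	S	2	1	1	1.435	0.015	80
B	O	1	0	0	1.370	0.020	30
B	F	1	0	0	1.390	0.018	20
P	P	1	0	0	2.210	0.025	10
S	S	1	0	0	2.050	0.020	30
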