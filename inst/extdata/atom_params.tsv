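type	rii	eps	vol	solpar	hbond	hb_rij	hb_eps
C	4.00	0.150	33.5103	-0.00143	none	0.00	0.0
A	4.00	0.150	33.5103	-0.00052	none	0.00	0.0
N	3.50	0.160	22.4493	-0.00162	none	0.00	0.0
NA	3.50	0.160	22.4493	-0.00162	acceptor	1.90	5.0
O	3.20	0.200	17.1573	-0.00251	acceptor	1.90	5.0
OA	3.20	0.200	17.1573	-0.00251	acceptor	1.90	5.0
H	2.00	0.020	0.0000	0.00051	none	0.00	0.0
HD	2.00	0.020	0.0000	0.00051	donor	0.00	0.0
S	4.00	0.200	33.5103	-0.00214	none	0.00	0.0
SA	4.00	0.200	33.5103	-0.00214	acceptor	2.50	1.0
P	4.20	0.200	38.7924	-0.00110	none	0.00	0.0
F	3.09	0.080	15.4480	-0.00110	none	0.00	0.0
Cl	4.09	0.276	35.8235	-0.00110	none	0.00	0.0
Br	4.33	0.389	42.5661	-0.00110	none	0.00	0.0
I	4.72	0.550	55.0585	-0.00110	none	0.00	0.0
ZN	1.48	0.550	1.7000	-0.00110	none	0.00	0.0
MG	1.30	0.875	1.5600	-0.00110	none	0.00	0.0
FE	1.30	0.010	1.8400	-0.00110	none	0.00	0.0
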