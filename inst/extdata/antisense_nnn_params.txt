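# Published next-nearest-neighbor antisense inhibition parameters
# 112 cell-culture knockdown experiments, four gene targets, two cell lines.
# Triplet values: percent reduction in net accumulated protein per circular
# triplet occurrence, at two-decimal printed precision. No covariance matrix
# accompanies these values.
[meta]
cell_baseline	T24
provenance	published fit of 112 antisense S-DNA experiments (printed two-decimal values)
[triplets]
term	estimate	std_error	n_data
AAA	2.98	2.08	30
AAC	5.96	1.45	32
AAG	0.48	1.82	36
AAU	-3.52	1.76	30
ACA	-3.78	1.67	48
ACC	4.63	2.79	25
ACG	1.82	1.69	28
ACU	3.81	1.66	33
AGA	3.23	1.99	40
AGC	3.86	1.46	39
AGG	4.83	1.82	52
AGU	-4.72	2.20	17
AUA	0.29	2.42	15
AUC	3.27	2.07	19
AUG	0.45	1.63	67
AUU	1.05	1.97	21
CAA	1.83	1.65	37
CAC	-1.51	1.31	46
CAG	-1.47	1.49	38
CAU	5.77	1.62	29
CCA	-0.99	2.14	26
CCC	-3.73	2.06	30
CCG	3.09	1.28	58
CCU	5.48	1.76	35
CGA	5.43	1.64	40
CGC	7.38	1.32	33
CGG	5.65	1.49	51
CGU	-5.02	1.96	19
CUA	13.27	2.79	14
CUC	1.37	1.75	31
CUG	0.87	1.75	44
CUU	-4.62	1.64	28
GAA	3.57	2.00	53
GAC	1.08	1.67	37
GAG	-2.19	1.07	63
GAU	4.87	1.71	47
GCA	6.89	1.64	46
GCC	-1.26	1.57	58
GCG	3.96	1.59	41
GCU	6.20	1.91	31
GGA	2.96	1.10	82
GGC	-2.70	1.10	56
GGG	2.06	1.28	76
GGU	8.28	1.99	30
GUA	-8.59	2.99	15
GUC	1.85	1.84	24
GUG	-3.40	1.46	42
GUU	10.43	2.95	18
UAA	-2.48	3.44	8
UAC	0.94	1.91	19
UAG	10.37	2.55	11
UAU	-2.06	2.69	16
UCA	2.50	1.75	30
UCC	4.20	1.98	36
UCG	4.57	2.47	16
UCU	-4.60	2.60	18
UGA	-4.28	1.93	38
UGC	7.26	1.14	48
UGG	-1.93	1.33	65
UGU	1.75	2.00	33
UUA	1.80	3.21	10
UUC	0.19	2.06	26
UUG	4.88	2.28	31
UUU	0.81	2.59	25
[covariates]
term	type	estimate	std_error	n_data
A549	cell	10.59	1.78	62
CRAF1	gene	3.65	2.33	52
BCL2	gene	-3.10	1.85	29
AKT2	gene	8.97	4.43	7
PKC-a	gene	-3.75	2.76	24
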