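# Per-element constants used by bond perception and radius assignment.
# covalent: single-bond covalent radii (Angstrom), Cordero et al. 2008.
# vdw: van der Waals radii (Angstrom), Bondi 1964 where defined, common
#      viewer defaults otherwise. mass in amu. r,g,b: CPK-like display
#      color in [0,1]. The X row is the fallback for unknown elements.
element	covalent	vdw	mass	r	g	b
H	0.31	1.20	1.008	1.00	1.00	1.00
D	0.31	1.20	2.014	0.90	1.00	1.00
C	0.76	1.70	12.011	0.50	0.50	0.50
N	0.71	1.55	14.007	0.19	0.31	0.97
O	0.66	1.52	15.999	1.00	0.05	0.05
P	1.07	1.80	30.974	1.00	0.50	0.00
S	1.05	1.80	32.06	1.00	0.78	0.20
F	0.57	1.47	18.998	0.56	0.88	0.31
CL	1.02	1.75	35.45	0.12	0.94	0.12
BR	1.20	1.85	79.904	0.65	0.16	0.16
I	1.39	1.98	126.904	0.58	0.00	0.58
NA	1.66	2.27	22.990	0.67	0.36	0.95
K	2.03	2.75	39.098	0.56	0.25	0.83
MG	1.41	1.73	24.305	0.54	1.00	0.00
CA	1.76	2.31	40.078	0.24	1.00	0.00
MN	1.39	2.05	54.938	0.61	0.48	0.78
FE	1.32	2.00	55.845	0.88	0.40	0.20
CO	1.26	2.00	58.933	0.94	0.56	0.63
NI	1.24	1.63	58.693	0.31	0.82	0.31
CU	1.32	1.40	63.546	0.78	0.50	0.20
ZN	1.22	1.39	65.38	0.49	0.50	0.69
SE	1.20	1.90	78.971	1.00	0.63	0.00
SI	1.11	2.10	28.085	0.94	0.78	0.63
B	0.84	1.92	10.81	1.00	0.71	0.71
LI	1.28	1.82	6.94	0.80	0.50	1.00
AL	1.21	1.84	26.982	0.75	0.65	0.65
X	0.77	1.70	0.0	1.00	0.08	0.58
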