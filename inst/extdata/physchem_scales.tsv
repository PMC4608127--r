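aa	hydrophilicity	flexibility	accessibility	polarity	exposed_surface	turns
A	2.1	0.984	0.3	8.1	0.615	0.66
R	4.2	1.008	-1.4	10.5	0.584	0.95
N	7.0	1.048	-0.5	11.6	0.776	1.56
D	10.0	1.068	-0.6	13.0	0.867	1.46
C	1.4	0.906	0.9	5.5	0.320	1.19
Q	6.0	1.037	-0.7	10.5	0.691	0.98
E	7.8	1.094	-0.7	12.3	0.881	0.74
G	5.7	1.031	0.3	9.0	0.714	1.56
H	2.1	0.950	-0.1	10.4	0.610	0.95
I	-8.0	0.927	0.7	5.2	0.273	0.47
L	-9.2	0.935	0.5	4.9	0.321	0.59
K	5.7	1.102	-1.8	11.3	0.930	1.01
M	-4.2	0.952	0.4	5.7	0.364	0.60
F	-9.2	0.915	0.5	5.2	0.303	0.60
P	2.1	1.049	-0.3	8.0	0.735	1.52
S	6.5	1.046	-0.1	9.2	0.693	1.43
T	5.2	0.997	-0.2	8.6	0.636	0.96
W	-10.0	0.904	0.3	5.4	0.411	0.96
Y	-1.9	0.929	-0.4	6.2	0.586	1.14
V	-3.7	0.931	0.6	5.9	0.283	0.50
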