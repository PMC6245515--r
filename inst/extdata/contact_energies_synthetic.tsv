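A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-1.235	-1.3167	-0.6167	-0.6167	-1.3517	-0.9783	-0.6517	-1.55	-0.57	-1.4683	-1.2467	-0.6167	-0.8383	-0.6167	-0.5	-0.9317	-0.9433	-1.515	-0.92	-0.8733
C	-1.3167	-2.4074	-0.6296	-0.6296	-1.4463	-1.0315	-0.6685	-1.6667	-0.5778	-1.5759	-1.3296	-0.6296	-0.8759	-0.6296	-0.5	-0.9796	-0.9926	-1.6278	-0.9667	-0.9148
D	-0.6167	-0.6296	-0.5185	-0.5185	-0.6352	-0.5759	-0.5241	-0.6667	-0.5111	-0.6537	-0.6185	-0.5185	-0.5537	-0.5185	-0.5	-0.5685	-0.5704	-0.6611	-0.5667	-0.5593
E	-0.6167	-0.6296	-0.5185	-0.5185	-0.6352	-0.5759	-0.5241	-0.6667	-0.5111	-0.6537	-0.6185	-0.5185	-0.5537	-0.5185	-0.5	-0.5685	-0.5704	-0.6611	-0.5667	-0.5593
F	-1.3517	-1.4463	-0.6352	-0.6352	-1.4869	-1.0543	-0.6757	-1.7167	-0.5811	-1.622	-1.3652	-0.6352	-0.892	-0.6352	-0.5	-1.0002	-1.0137	-1.6761	-0.9867	-0.9326
G	-0.9783	-1.0315	-0.5759	-0.5759	-1.0543	-0.8113	-0.5987	-1.1833	-0.5456	-1.1302	-0.9859	-0.5759	-0.7202	-0.5759	-0.5	-0.7809	-0.7885	-1.1606	-0.7733	-0.743
H	-0.6517	-0.6685	-0.5241	-0.5241	-0.6757	-0.5987	-0.5313	-0.7167	-0.5144	-0.6998	-0.6541	-0.5241	-0.5698	-0.5241	-0.5	-0.5891	-0.5915	-0.7094	-0.5867	-0.577
I	-1.55	-1.6667	-0.6667	-0.6667	-1.7167	-1.1833	-0.7167	-2	-0.6	-1.8833	-1.5667	-0.6667	-0.9833	-0.6667	-0.5	-1.1167	-1.1333	-1.95	-1.1	-1.0333
K	-0.57	-0.5778	-0.5111	-0.5111	-0.5811	-0.5456	-0.5144	-0.6	-0.5067	-0.5922	-0.5711	-0.5111	-0.5322	-0.5111	-0.5	-0.5411	-0.5422	-0.5967	-0.54	-0.5356
L	-1.4683	-1.5759	-0.6537	-0.6537	-1.622	-1.1302	-0.6998	-1.8833	-0.5922	-1.7757	-1.4837	-0.6537	-0.9457	-0.6537	-0.5	-1.0687	-1.0841	-1.8372	-1.0533	-0.9919
M	-1.2467	-1.3296	-0.6185	-0.6185	-1.3652	-0.9859	-0.6541	-1.5667	-0.5711	-1.4837	-1.2585	-0.6185	-0.8437	-0.6185	-0.5	-0.9385	-0.9504	-1.5311	-0.9267	-0.8793
N	-0.6167	-0.6296	-0.5185	-0.5185	-0.6352	-0.5759	-0.5241	-0.6667	-0.5111	-0.6537	-0.6185	-0.5185	-0.5537	-0.5185	-0.5	-0.5685	-0.5704	-0.6611	-0.5667	-0.5593
P	-0.8383	-0.8759	-0.5537	-0.5537	-0.892	-0.7202	-0.5698	-0.9833	-0.5322	-0.9457	-0.8437	-0.5537	-0.6557	-0.5537	-0.5	-0.6987	-0.7041	-0.9672	-0.6933	-0.6719
Q	-0.6167	-0.6296	-0.5185	-0.5185	-0.6352	-0.5759	-0.5241	-0.6667	-0.5111	-0.6537	-0.6185	-0.5185	-0.5537	-0.5185	-0.5	-0.5685	-0.5704	-0.6611	-0.5667	-0.5593
R	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5	-0.5
S	-0.9317	-0.9796	-0.5685	-0.5685	-1.0002	-0.7809	-0.5891	-1.1167	-0.5411	-1.0687	-0.9385	-0.5685	-0.6987	-0.5685	-0.5	-0.7535	-0.7604	-1.0961	-0.7467	-0.7193
T	-0.9433	-0.9926	-0.5704	-0.5704	-1.0137	-0.7885	-0.5915	-1.1333	-0.5422	-1.0841	-0.9504	-0.5704	-0.7041	-0.5704	-0.5	-0.7604	-0.7674	-1.1122	-0.7533	-0.7252
V	-1.515	-1.6278	-0.6611	-0.6611	-1.6761	-1.1606	-0.7094	-1.95	-0.5967	-1.8372	-1.5311	-0.6611	-0.9672	-0.6611	-0.5	-1.0961	-1.1122	-1.9017	-1.08	-1.0156
W	-0.92	-0.9667	-0.5667	-0.5667	-0.9867	-0.7733	-0.5867	-1.1	-0.54	-1.0533	-0.9267	-0.5667	-0.6933	-0.5667	-0.5	-0.7467	-0.7533	-1.08	-0.74	-0.7133
Y	-0.8733	-0.9148	-0.5593	-0.5593	-0.9326	-0.743	-0.577	-1.0333	-0.5356	-0.9919	-0.8793	-0.5593	-0.6719	-0.5593	-0.5	-0.7193	-0.7252	-1.0156	-0.7133	-0.6896
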