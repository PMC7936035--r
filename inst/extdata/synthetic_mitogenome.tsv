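label	strand	start	end	type
cox1	H	0	234	PCG
S2	L	234	249	tRNA
D	H	249	264	tRNA
cox2	H	264	366	PCG
K	H	366	381	tRNA
atp8	H	381	471	PCG
atp6	H	471	573	PCG
cox3	H	573	690	PCG
G	H	690	705	tRNA
nad3	H	705	795	PCG
R	H	795	810	tRNA
nad4L	H	810	900	PCG
nad4	H	900	1107	PCG
H	H	1107	1122	tRNA
S1	H	1122	1137	tRNA
L1	H	1137	1152	tRNA
nad5	H	1152	1428	PCG
nad6	L	1428	1518	PCG
E	L	1518	1533	tRNA
cob	H	1533	1704	PCG
T	H	1704	1719	tRNA
P	L	1719	1734	tRNA
CoRe	H	1734	1874	control_region
F	H	1874	1889	tRNA
rrnS	H	1889	2031	rRNA
V	H	2031	2046	tRNA
rrnL	H	2046	2298	rRNA
L2	H	2298	2313	tRNA
nad1	H	2313	2460	PCG
I	H	2460	2475	tRNA
Q	L	2475	2490	tRNA
M	H	2490	2505	tRNA
nad2	H	2505	2661	PCG
W	H	2661	2676	tRNA
A	L	2676	2691	tRNA
N	L	2691	2706	tRNA
OL	H	2706	2721	origin
C	L	2721	2736	tRNA
Y	L	2736	2751	tRNA
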