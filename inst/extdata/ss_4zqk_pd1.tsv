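domain	res_start	res_end	kind
NtermA' loop	116	126	loop
A' strand	127	129	strand
A'A loop	130	131	loop
A strand	132	136	strand
AB loop	137	140	loop
B strand	141	146	strand
BC loop	147	152	loop
C strand	153	161	strand
CC' loop	162	166	loop
C' strand	167	173	strand
C'D loop	174	185	loop
D strand	186	190	strand
DE loop	191	195	loop
E strand	196	201	strand
EF loop	202	209	loop
F strand	210	220	strand
FG loop	221	223	loop
G strand	224	227	strand
GG' loop	228	230	loop
G' strand	231	236	strand
G'rest loop	237	240	loop
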