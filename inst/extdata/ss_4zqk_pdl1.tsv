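domain	res_start	res_end	kind
NtermA loop	1	9	loop
A strand	10	14	strand
AB loop	15	18	loop
B strand	19	24	strand
BH1 loop	25	31	loop
Helix1	32	35	helix
H1C loop	36	36	loop
C strand	37	42	strand
CC' loop	43	44	loop
C' strand	45	51	strand
C'C'' loop	52	53	loop
C'' strand	54	55	strand
C''H2 loop	56	56	loop
Helix2	57	65	helix
H2D loop	66	67	loop
D strand	68	70	strand
DH3 loop	71	71	loop
Helix3	72	77	helix
H3E loop	78	78	loop
E strand	79	84	strand
EH4 loop	85	87	loop
Helix4	88	92	helix
F strand	93	100	strand
FG loop	101	103	loop
G strand	104	114	strand
Grest loop	115	115	loop
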