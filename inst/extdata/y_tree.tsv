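node	parent	markers
Y	ROOT
A	Y	M91:T>-
B	Y	M60:C>T
C	Y	M130:C>T
DE	Y	M203:G>A
D	DE	M174:T>C
E	DE	M96:C>G:rs9306841:20238386
E1b1a	E	M2:A>G
E1b1b	E	M215:T>C:rs2032654:13977218
E1b1b1a1	E1b1b	M78:G>A:na:20352691
E1b1b1b1	E1b1b	M81:G>A:rs2032640:20351960
E1b1b1c	E1b1b	M123:C>T:na:20223974
F	Y	M89:A>G:rs2032652:20376701
G	F	M201:G>T:rs2032636:13536923
G1	G	M285:G>C:rs13447378:21151128
G2a	G	P15:G>A:na:21653414
G2c	G	M377:A>G:na:13536827
H	F	M69:T>C
IJK	F	M522:A>G
IJ	IJK	M429:T>A
I	IJ	M170:A>C:rs2032597:13357186
I1	I	M307:G>A:rs13447354:21160339
I2a1a	I	M26:C>T:rs2032629:20325209
I2b+I2c	I
J	IJ	M304:A>C:rs13447352:21159241
J1	J	M267:T>G
J2	J	M172:T>G:rs2032604:13479028
K	IJK	M9:C>G:rs3900:20189645
L	K	M20:A>G
T1	K	M70:T>G:rs2032672:20353269
NO	K	M214:A>G:rs2032674:13981319
N	NO	M231:C>T:rs9341278:13979118
N1c	N	M46:T>C:rs34442126:13431977
O	NO	M175:A>-
P	K	M74:C>T:rs2032635:20349155
Q	P	M242:C>T:rs8179021:13527976
R	P	M207:T>C:rs2032658:14091377
R1	R	M173:A>C:rs2032624:13535818
R1a+R1*	R1
R1b	R1	M343:C>A:rs9786184:2947824
R1b1a2	R1b	M269:T>C:rs9786153:21148755
R1b1b+R1b*	R1b
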