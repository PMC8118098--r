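grapheme,position_class,context_set
C,any,E|I|Y
G,any,E|I|Y
I,word_initial,
I,word_final,
Y,syllable_final,
A,any,
B,any,
C,any,
D,any,
E,any,
F,any,
G,any,
H,any,
I,any,
J,any,
K,any,
L,any,
M,any,
N,any,
O,any,
P,any,
Q,any,
R,any,
S,any,
T,any,
U,any,
V,any,
W,any,
X,any,
Y,any,
Z,any,
CH,any,
SH,any,
TH,any,
PH,any,
WH,any,
GH,any,
CK,any,
NG,syllable_final,
QU,any,
DGE,word_final,
TCH,any,
IGH,any,
AI,any,
AY,any,
AU,any,
AW,any,
EA,any,
EE,any,
EI,any,
EY,any,
EW,any,
IE,any,
OA,any,
OE,any,
OI,any,
OO,any,
OU,any,
OW,any,
OY,any,
UE,any,
UI,any,
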