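# ProtOr group radii for protein and nucleic-acid atoms.
# Carbon classes are apolar; N/O/S/P/Se classes are polar.
# Phosphorus 1.8 A and selenium 1.9 A supplement the original set.

types:
C_ALI 1.88 apolar
C_ARO 1.76 apolar
C_CAR 1.61 apolar
N_AMD 1.64 polar
O_CAR 1.42 polar
O_HYD 1.46 polar
S_THI 1.77 polar
P_PHO 1.80 polar
SE_SE 1.90 polar

atoms:
ALA N    N_AMD
ALA CA   C_ALI
ALA C    C_CAR
ALA O    O_CAR
ALA OXT  O_HYD
ALA CB   C_ALI
ARG N    N_AMD
ARG CA   C_ALI
ARG C    C_CAR
ARG O    O_CAR
ARG OXT  O_HYD
ARG CB   C_ALI
ARG CG   C_ALI
ARG CD   C_ALI
ARG NE   N_AMD
ARG CZ   C_CAR
ARG NH1  N_AMD
ARG NH2  N_AMD
ASN N    N_AMD
ASN CA   C_ALI
ASN C    C_CAR
ASN O    O_CAR
ASN OXT  O_HYD
ASN CB   C_ALI
ASN CG   C_CAR
ASN OD1  O_CAR
ASN ND2  N_AMD
ASP N    N_AMD
ASP CA   C_ALI
ASP C    C_CAR
ASP O    O_CAR
ASP OXT  O_HYD
ASP CB   C_ALI
ASP CG   C_CAR
ASP OD1  O_CAR
ASP OD2  O_CAR
CYS N    N_AMD
CYS CA   C_ALI
CYS C    C_CAR
CYS O    O_CAR
CYS OXT  O_HYD
CYS CB   C_ALI
CYS SG   S_THI
GLN N    N_AMD
GLN CA   C_ALI
GLN C    C_CAR
GLN O    O_CAR
GLN OXT  O_HYD
GLN CB   C_ALI
GLN CG   C_ALI
GLN CD   C_CAR
GLN OE1  O_CAR
GLN NE2  N_AMD
GLU N    N_AMD
GLU CA   C_ALI
GLU C    C_CAR
GLU O    O_CAR
GLU OXT  O_HYD
GLU CB   C_ALI
GLU CG   C_ALI
GLU CD   C_CAR
GLU OE1  O_CAR
GLU OE2  O_CAR
GLY N    N_AMD
GLY CA   C_ALI
GLY C    C_CAR
GLY O    O_CAR
GLY OXT  O_HYD
HIS N    N_AMD
HIS CA   C_ALI
HIS C    C_CAR
HIS O    O_CAR
HIS OXT  O_HYD
HIS CB   C_ALI
HIS CG   C_CAR
HIS ND1  N_AMD
HIS CD2  C_ARO
HIS CE1  C_ARO
HIS NE2  N_AMD
ILE N    N_AMD
ILE CA   C_ALI
ILE C    C_CAR
ILE O    O_CAR
ILE OXT  O_HYD
ILE CB   C_ALI
ILE CG1  C_ALI
ILE CG2  C_ALI
ILE CD1  C_ALI
ILE CD   C_ALI
LEU N    N_AMD
LEU CA   C_ALI
LEU C    C_CAR
LEU O    O_CAR
LEU OXT  O_HYD
LEU CB   C_ALI
LEU CG   C_ALI
LEU CD1  C_ALI
LEU CD2  C_ALI
LYS N    N_AMD
LYS CA   C_ALI
LYS C    C_CAR
LYS O    O_CAR
LYS OXT  O_HYD
LYS CB   C_ALI
LYS CG   C_ALI
LYS CD   C_ALI
LYS CE   C_ALI
LYS NZ   N_AMD
MET N    N_AMD
MET CA   C_ALI
MET C    C_CAR
MET O    O_CAR
MET OXT  O_HYD
MET CB   C_ALI
MET CG   C_ALI
MET SD   S_THI
MET CE   C_ALI
PHE N    N_AMD
PHE CA   C_ALI
PHE C    C_CAR
PHE O    O_CAR
PHE OXT  O_HYD
PHE CB   C_ALI
PHE CG   C_CAR
PHE CD1  C_ARO
PHE CD2  C_ARO
PHE CE1  C_ARO
PHE CE2  C_ARO
PHE CZ   C_ARO
PRO N    N_AMD
PRO CA   C_ALI
PRO C    C_CAR
PRO O    O_CAR
PRO OXT  O_HYD
PRO CB   C_ALI
PRO CG   C_ALI
PRO CD   C_ALI
SER N    N_AMD
SER CA   C_ALI
SER C    C_CAR
SER O    O_CAR
SER OXT  O_HYD
SER CB   C_ALI
SER OG   O_HYD
THR N    N_AMD
THR CA   C_ALI
THR C    C_CAR
THR O    O_CAR
THR OXT  O_HYD
THR CB   C_ALI
THR OG1  O_HYD
THR CG2  C_ALI
TRP N    N_AMD
TRP CA   C_ALI
TRP C    C_CAR
TRP O    O_CAR
TRP OXT  O_HYD
TRP CB   C_ALI
TRP CG   C_CAR
TRP CD1  C_ARO
TRP CD2  C_CAR
TRP NE1  N_AMD
TRP CE2  C_CAR
TRP CE3  C_ARO
TRP CZ2  C_ARO
TRP CZ3  C_ARO
TRP CH2  C_ARO
TYR N    N_AMD
TYR CA   C_ALI
TYR C    C_CAR
TYR O    O_CAR
TYR OXT  O_HYD
TYR CB   C_ALI
TYR CG   C_CAR
TYR CD1  C_ARO
TYR CD2  C_ARO
TYR CE1  C_ARO
TYR CE2  C_ARO
TYR CZ   C_CAR
TYR OH   O_HYD
VAL N    N_AMD
VAL CA   C_ALI
VAL C    C_CAR
VAL O    O_CAR
VAL OXT  O_HYD
VAL CB   C_ALI
VAL CG1  C_ALI
VAL CG2  C_ALI
SEC N    N_AMD
SEC CA   C_ALI
SEC C    C_CAR
SEC O    O_CAR
SEC OXT  O_HYD
SEC CB   C_ALI
SEC SE   SE_SE
MSE N    N_AMD
MSE CA   C_ALI
MSE C    C_CAR
MSE O    O_CAR
MSE OXT  O_HYD
MSE CB   C_ALI
MSE CG   C_ALI
MSE SE   SE_SE
MSE CE   C_ALI
PYL N    N_AMD
PYL CA   C_ALI
PYL C    C_CAR
PYL O    O_CAR
PYL OXT  O_HYD
PYL CB   C_ALI
PYL CG   C_ALI
PYL CD   C_ALI
PYL CE   C_ALI
PYL NZ   N_AMD
PYL C2   C_CAR
PYL O2   O_CAR
PYL CA2  C_ALI
PYL CB2  C_ALI
PYL CG2  C_ALI
PYL CD2  C_ALI
PYL CE2  C_CAR
PYL N2   N_AMD
A   P    P_PHO
A   OP1  O_CAR
A   OP2  O_CAR
A   OP3  O_CAR
A   O1P  O_CAR
A   O2P  O_CAR
A   O3P  O_CAR
A   O5'  O_CAR
A   O4'  O_CAR
A   O3'  O_CAR
A   O2'  O_HYD
A   C1'  C_ALI
A   C2'  C_ALI
A   C3'  C_ALI
A   C4'  C_ALI
A   C5'  C_ALI
A   N9   N_AMD
A   C8   C_ARO
A   N7   N_AMD
A   C5   C_CAR
A   C6   C_CAR
A   N6   N_AMD
A   N1   N_AMD
A   C2   C_ARO
A   N3   N_AMD
A   C4   C_CAR
G   P    P_PHO
G   OP1  O_CAR
G   OP2  O_CAR
G   OP3  O_CAR
G   O1P  O_CAR
G   O2P  O_CAR
G   O3P  O_CAR
G   O5'  O_CAR
G   O4'  O_CAR
G   O3'  O_CAR
G   O2'  O_HYD
G   C1'  C_ALI
G   C2'  C_ALI
G   C3'  C_ALI
G   C4'  C_ALI
G   C5'  C_ALI
G   N9   N_AMD
G   C8   C_ARO
G   N7   N_AMD
G   C5   C_CAR
G   C6   C_CAR
G   O6   O_CAR
G   N1   N_AMD
G   C2   C_CAR
G   N2   N_AMD
G   N3   N_AMD
G   C4   C_CAR
C   P    P_PHO
C   OP1  O_CAR
C   OP2  O_CAR
C   OP3  O_CAR
C   O1P  O_CAR
C   O2P  O_CAR
C   O3P  O_CAR
C   O5'  O_CAR
C   O4'  O_CAR
C   O3'  O_CAR
C   O2'  O_HYD
C   C1'  C_ALI
C   C2'  C_ALI
C   C3'  C_ALI
C   C4'  C_ALI
C   C5'  C_ALI
C   N1   N_AMD
C   C2   C_CAR
C   O2   O_CAR
C   N3   N_AMD
C   C4   C_CAR
C   N4   N_AMD
C   C5   C_ARO
C   C6   C_ARO
U   P    P_PHO
U   OP1  O_CAR
U   OP2  O_CAR
U   OP3  O_CAR
U   O1P  O_CAR
U   O2P  O_CAR
U   O3P  O_CAR
U   O5'  O_CAR
U   O4'  O_CAR
U   O3'  O_CAR
U   O2'  O_HYD
U   C1'  C_ALI
U   C2'  C_ALI
U   C3'  C_ALI
U   C4'  C_ALI
U   C5'  C_ALI
U   N1   N_AMD
U   C2   C_CAR
U   O2   O_CAR
U   N3   N_AMD
U   C4   C_CAR
U   O4   O_CAR
U   C5   C_ARO
U   C6   C_ARO
T   P    P_PHO
T   OP1  O_CAR
T   OP2  O_CAR
T   OP3  O_CAR
T   O1P  O_CAR
T   O2P  O_CAR
T   O3P  O_CAR
T   O5'  O_CAR
T   O4'  O_CAR
T   O3'  O_CAR
T   O2'  O_HYD
T   C1'  C_ALI
T   C2'  C_ALI
T   C3'  C_ALI
T   C4'  C_ALI
T   C5'  C_ALI
T   N1   N_AMD
T   C2   C_CAR
T   O2   O_CAR
T   N3   N_AMD
T   C4   C_CAR
T   O4   O_CAR
T   C5   C_CAR
T   C6   C_ARO
T   C7   C_ALI
T   C5M  C_ALI
DA  P    P_PHO
DA  OP1  O_CAR
DA  OP2  O_CAR
DA  OP3  O_CAR
DA  O1P  O_CAR
DA  O2P  O_CAR
DA  O3P  O_CAR
DA  O5'  O_CAR
DA  O4'  O_CAR
DA  O3'  O_CAR
DA  O2'  O_HYD
DA  C1'  C_ALI
DA  C2'  C_ALI
DA  C3'  C_ALI
DA  C4'  C_ALI
DA  C5'  C_ALI
DA  N9   N_AMD
DA  C8   C_ARO
DA  N7   N_AMD
DA  C5   C_CAR
DA  C6   C_CAR
DA  N6   N_AMD
DA  N1   N_AMD
DA  C2   C_ARO
DA  N3   N_AMD
DA  C4   C_CAR
DG  P    P_PHO
DG  OP1  O_CAR
DG  OP2  O_CAR
DG  OP3  O_CAR
DG  O1P  O_CAR
DG  O2P  O_CAR
DG  O3P  O_CAR
DG  O5'  O_CAR
DG  O4'  O_CAR
DG  O3'  O_CAR
DG  O2'  O_HYD
DG  C1'  C_ALI
DG  C2'  C_ALI
DG  C3'  C_ALI
DG  C4'  C_ALI
DG  C5'  C_ALI
DG  N9   N_AMD
DG  C8   C_ARO
DG  N7   N_AMD
DG  C5   C_CAR
DG  C6   C_CAR
DG  O6   O_CAR
DG  N1   N_AMD
DG  C2   C_CAR
DG  N2   N_AMD
DG  N3   N_AMD
DG  C4   C_CAR
DC  P    P_PHO
DC  OP1  O_CAR
DC  OP2  O_CAR
DC  OP3  O_CAR
DC  O1P  O_CAR
DC  O2P  O_CAR
DC  O3P  O_CAR
DC  O5'  O_CAR
DC  O4'  O_CAR
DC  O3'  O_CAR
DC  O2'  O_HYD
DC  C1'  C_ALI
DC  C2'  C_ALI
DC  C3'  C_ALI
DC  C4'  C_ALI
DC  C5'  C_ALI
DC  N1   N_AMD
DC  C2   C_CAR
DC  O2   O_CAR
DC  N3   N_AMD
DC  C4   C_CAR
DC  N4   N_AMD
DC  C5   C_ARO
DC  C6   C_ARO
DT  P    P_PHO
DT  OP1  O_CAR
DT  OP2  O_CAR
DT  OP3  O_CAR
DT  O1P  O_CAR
DT  O2P  O_CAR
DT  O3P  O_CAR
DT  O5'  O_CAR
DT  O4'  O_CAR
DT  O3'  O_CAR
DT  O2'  O_HYD
DT  C1'  C_ALI
DT  C2'  C_ALI
DT  C3'  C_ALI
DT  C4'  C_ALI
DT  C5'  C_ALI
DT  N1   N_AMD
DT  C2   C_CAR
DT  O2   O_CAR
DT  N3   N_AMD
DT  C4   C_CAR
DT  O4   O_CAR
DT  C5   C_CAR
DT  C6   C_ARO
DT  C7   C_ALI
DT  C5M  C_ALI
ACE C    C_CAR
ACE O    O_CAR
ACE CH3  C_ALI
ACE CA   C_ALI
NH2 N    N_AMD
HOH O    O_HYD
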