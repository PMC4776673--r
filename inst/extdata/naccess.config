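# NACCESS-compatible radius subset (protein atoms only).

types:
C_ALI 1.87 apolar
C_ARO 1.76 apolar
N_AMD 1.65 polar
O_ALL 1.40 polar
S_ALL 1.85 polar

atoms:
ALA N    N_AMD
ALA CA   C_ALI
ALA C    C_ARO
ALA O    O_ALL
ALA OXT  O_ALL
ALA CB   C_ALI
ARG N    N_AMD
ARG CA   C_ALI
ARG C    C_ARO
ARG O    O_ALL
ARG OXT  O_ALL
ARG CB   C_ALI
ARG CG   C_ALI
ARG CD   C_ALI
ARG NE   N_AMD
ARG CZ   C_ARO
ARG NH1  N_AMD
ARG NH2  N_AMD
ASN N    N_AMD
ASN CA   C_ALI
ASN C    C_ARO
ASN O    O_ALL
ASN OXT  O_ALL
ASN CB   C_ALI
ASN CG   C_ARO
ASN OD1  O_ALL
ASN ND2  N_AMD
ASP N    N_AMD
ASP CA   C_ALI
ASP C    C_ARO
ASP O    O_ALL
ASP OXT  O_ALL
ASP CB   C_ALI
ASP CG   C_ARO
ASP OD1  O_ALL
ASP OD2  O_ALL
CYS N    N_AMD
CYS CA   C_ALI
CYS C    C_ARO
CYS O    O_ALL
CYS OXT  O_ALL
CYS CB   C_ALI
CYS SG   S_ALL
GLN N    N_AMD
GLN CA   C_ALI
GLN C    C_ARO
GLN O    O_ALL
GLN OXT  O_ALL
GLN CB   C_ALI
GLN CG   C_ALI
GLN CD   C_ARO
GLN OE1  O_ALL
GLN NE2  N_AMD
GLU N    N_AMD
GLU CA   C_ALI
GLU C    C_ARO
GLU O    O_ALL
GLU OXT  O_ALL
GLU CB   C_ALI
GLU CG   C_ALI
GLU CD   C_ARO
GLU OE1  O_ALL
GLU OE2  O_ALL
GLY N    N_AMD
GLY CA   C_ALI
GLY C    C_ARO
GLY O    O_ALL
GLY OXT  O_ALL
HIS N    N_AMD
HIS CA   C_ALI
HIS C    C_ARO
HIS O    O_ALL
HIS OXT  O_ALL
HIS CB   C_ALI
HIS CG   C_ARO
HIS ND1  N_AMD
HIS CD2  C_ARO
HIS CE1  C_ARO
HIS NE2  N_AMD
ILE N    N_AMD
ILE CA   C_ALI
ILE C    C_ARO
ILE O    O_ALL
ILE OXT  O_ALL
ILE CB   C_ALI
ILE CG1  C_ALI
ILE CG2  C_ALI
ILE CD1  C_ALI
ILE CD   C_ALI
LEU N    N_AMD
LEU CA   C_ALI
LEU C    C_ARO
LEU O    O_ALL
LEU OXT  O_ALL
LEU CB   C_ALI
LEU CG   C_ALI
LEU CD1  C_ALI
LEU CD2  C_ALI
LYS N    N_AMD
LYS CA   C_ALI
LYS C    C_ARO
LYS O    O_ALL
LYS OXT  O_ALL
LYS CB   C_ALI
LYS CG   C_ALI
LYS CD   C_ALI
LYS CE   C_ALI
LYS NZ   N_AMD
MET N    N_AMD
MET CA   C_ALI
MET C    C_ARO
MET O    O_ALL
MET OXT  O_ALL
MET CB   C_ALI
MET CG   C_ALI
MET SD   S_ALL
MET CE   C_ALI
PHE N    N_AMD
PHE CA   C_ALI
PHE C    C_ARO
PHE O    O_ALL
PHE OXT  O_ALL
PHE CB   C_ALI
PHE CG   C_ARO
PHE CD1  C_ARO
PHE CD2  C_ARO
PHE CE1  C_ARO
PHE CE2  C_ARO
PHE CZ   C_ARO
PRO N    N_AMD
PRO CA   C_ALI
PRO C    C_ARO
PRO O    O_ALL
PRO OXT  O_ALL
PRO CB   C_ALI
PRO CG   C_ALI
PRO CD   C_ALI
SER N    N_AMD
SER CA   C_ALI
SER C    C_ARO
SER O    O_ALL
SER OXT  O_ALL
SER CB   C_ALI
SER OG   O_ALL
THR N    N_AMD
THR CA   C_ALI
THR C    C_ARO
THR O    O_ALL
THR OXT  O_ALL
THR CB   C_ALI
THR OG1  O_ALL
THR CG2  C_ALI
TRP N    N_AMD
TRP CA   C_ALI
TRP C    C_ARO
TRP O    O_ALL
TRP OXT  O_ALL
TRP CB   C_ALI
TRP CG   C_ARO
TRP CD1  C_ARO
TRP CD2  C_ARO
TRP NE1  N_AMD
TRP CE2  C_ARO
TRP CE3  C_ARO
TRP CZ2  C_ARO
TRP CZ3  C_ARO
TRP CH2  C_ARO
TYR N    N_AMD
TYR CA   C_ALI
TYR C    C_ARO
TYR O    O_ALL
TYR OXT  O_ALL
TYR CB   C_ALI
TYR CG   C_ARO
TYR CD1  C_ARO
TYR CD2  C_ARO
TYR CE1  C_ARO
TYR CE2  C_ARO
TYR CZ   C_ARO
TYR OH   O_ALL
VAL N    N_AMD
VAL CA   C_ALI
VAL C    C_ARO
VAL O    O_ALL
VAL OXT  O_ALL
VAL CB   C_ALI
VAL CG1  C_ALI
VAL CG2  C_ALI
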