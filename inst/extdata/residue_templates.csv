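resname,atom,role
ASP,OD1,anion
ASP,OD2,anion
GLU,OE1,anion
GLU,OE2,anion
LYS,NZ,cation
ARG,NE,cation
ARG,NH1,cation
ARG,NH2,cation
HIS,ND1,donor
HIS,NE2,acceptor
SER,OG,donor
SER,OG,acceptor
THR,OG1,donor
THR,OG1,acceptor
TYR,OH,donor
TYR,OH,acceptor
ASN,OD1,acceptor
ASN,ND2,donor
GLN,OE1,acceptor
GLN,NE2,donor
TRP,NE1,donor
CYS,SG,donor
MET,SD,apolar
BCK,O,acceptor
BCK,N,donor
PHE,ring,aromatic_ring
TYR,ring,aromatic_ring
TRP,ring,aromatic_ring
HIS,ring,aromatic_ring
POPC,N,cation
POPC,P,acceptor
POPC,O11,anion
POPC,O11,acceptor
POPC,O12,anion
POPC,O12,acceptor
POPC,O13,acceptor
POPC,O14,acceptor
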