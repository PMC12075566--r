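ftype,rule,placement,param,enabled,description
R,aromatic_ring,ring_centroid_normal,,TRUE,planar 5-7 ring of C/N/O/S with aromatic or alternating bond orders; placed at ring centroid with direction along the ring normal
P,positive_atom,atom,,TRUE,atom with formal charge > 0 (protonated amines/amidinium/guanidinium nitrogens); placed at the charged atom
N,carboxylate,oxygen_midpoint,,TRUE,carboxylate C(=O)O- group; placed at the midpoint of the two oxygens
N,negative_atom,atom,,TRUE,any other atom with formal charge < 0; placed at the atom
A,acceptor_atom,atom_lonepair,,TRUE,N or O with formal charge <= 0 and a free lone pair; direction along the idealized lone-pair vector
D,donor_atom,atom_h_vector,,TRUE,N or O bearing at least one hydrogen (charged or neutral); direction along the mean X-H vector
H,apolar_cluster,cluster_centroid,2,TRUE,connected cluster (>= param atoms) of non-aromatic carbons bonded only to C/H/halogen; placed at the cluster centroid
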