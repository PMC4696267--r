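CCO ethanol
CC(=O)O acetic_acid
c1ccccc1 benzene
Cc1ccccc1 toluene
c1ccncc1 pyridine
c1cc[nH]c1 pyrrole
CC(=O)Oc1ccccc1C(=O)O aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
CC(=O)Nc1ccc(O)cc1 paracetamol
OCC(O)CO glycerol
C1CCCCC1 cyclohexane
O=C(O)c1ccccc1O salicylic_acid
CCN(CC)CC triethylamine
CSCC(N)C(=O)O methionine_like
NC(=O)c1ccccc1 benzamide
Clc1ccccc1 chlorobenzene
OC(=O)CC(O)(CC(=O)O)C(=O)O citric_acid
CC(N)Cc1ccccc1 amphetamine_like
O=S(=O)(N)c1ccccc1 benzenesulfonamide
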