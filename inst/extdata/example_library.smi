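# Small hand-written SMILES set for parser and fingerprint tests.
# Format: SMILES<ws>id[<ws>name]
CCO ethanol Ethanol
c1ccccc1 benzene Benzene
CC(=O)Oc1ccccc1C(=O)O aspirin Aspirin
CN1C=NC2=C1C(=O)N(C)C(=O)N2C caffeine Caffeine
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen Ibuprofen
C1CCCCC1 cyclohexane Cyclohexane
OC(=O)c1ccccc1 benzoic_acid Benzoic_acid
CCN(CC)CC triethylamine Triethylamine
Oc1ccc(cc1)C=CC(=O)O coumaric_acid Coumaric_acid
CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2=O androstenedione Androstenedione
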