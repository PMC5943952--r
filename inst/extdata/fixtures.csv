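id,smiles,alkane_C,unsatHC_C,h_acceptor
tetrafluoroborate,[B-](F)(F)(F)F,0,0,0
pyridinium,c1cc[nH+]cc1,0,0,0
2-methylimidazolium,Cc1[nH]cc[nH+]1,0,0,0
1-methylimidazolium,Cn1cc[nH+]c1,0,0,0
1-methylpyridinium,C[n+]1ccccc1,0,0,0
bistriflamide,FC(F)(F)S(=O)(=O)[N-]S(=O)(=O)C(F)(F)F,0,0,0
tetramethylphosphonium,C[P+](C)(C)C,0,0,0
hexafluorophosphate,F[P-](F)(F)(F)(F)F,0,0,0
methylsulfonate,CS(=O)(=O)[O-],0,0,0
methanol,CO,0,0,0
ethanol,CCO,0,0,0
hexane,CCCCCC,6,0,0
benzene,c1ccccc1,0,6,0
toluene,Cc1ccccc1,0,7,0
acetic_acid,CC(=O)O,0,0,0
phenol,Oc1ccccc1,0,0,0
salicylaldehyde,O=Cc1ccccc1O,0,0,1
ethylene_glycol,OCCO,0,0,1
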