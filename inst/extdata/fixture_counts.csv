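id,atom_type,neighbors,count
tetrafluoroborate,B(-),F4,1
pyridinium,C aromatic,H:C:N(+),2
pyridinium,C aromatic,H:C2,3
pyridinium,N(+) aromatic,H:C2,1
2-methylimidazolium,C sp3,H3C(+),1
2-methylimidazolium,C(+) aromatic,C:N2,1
2-methylimidazolium,N aromatic,HC:C(+),2
2-methylimidazolium,C sp2,H=CN,2
1-methylimidazolium,C sp3,H3N,1
1-methylimidazolium,N aromatic,C2:C(+),1
1-methylimidazolium,C(+) aromatic,H:N2,1
1-methylimidazolium,N aromatic,HC:C(+),1
1-methylimidazolium,C sp2,H=CN,2
1-methylpyridinium,C sp3,H3N(+),1
1-methylpyridinium,N(+) aromatic,C:C2,1
1-methylpyridinium,C aromatic,H:C:N(+),2
1-methylpyridinium,C aromatic,H:C2,3
bistriflamide,C sp3,SF3,2
bistriflamide,S4,CN=O2(-),2
bistriflamide,N(-),S2,1
tetramethylphosphonium,C sp3,H3P(+),4
tetramethylphosphonium,P(+),C4,1
hexafluorophosphate,P(-),F6,1
methylsulfonate,C sp3,H3S,1
methylsulfonate,S4,CO=O2(-),1
methanol,C sp3,H3O,1
methanol,O,HC,1
ethanol,C sp3,H3C,1
ethanol,C sp3,H2CO,1
ethanol,O,HC,1
hexane,C sp3,H3C,2
hexane,C sp3,H2C2,4
benzene,C aromatic,H:C2,6
toluene,C sp3,H3C,1
toluene,C aromatic,C:C2,1
toluene,C aromatic,H:C2,5
acetic_acid,C sp3,H3C,1
acetic_acid,C sp2,CO=O,1
acetic_acid,O,HC(pi),1
phenol,C aromatic,:C2O,1
phenol,C aromatic,H:C2,5
phenol,O,HC(pi),1
salicylaldehyde,C sp2,HC=O,1
salicylaldehyde,C aromatic,C:C2,1
salicylaldehyde,C aromatic,:C2O,1
salicylaldehyde,C aromatic,H:C2,4
salicylaldehyde,O,HC(pi),1
ethylene_glycol,C sp3,H2CO,2
ethylene_glycol,O,HC,2
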