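name,smiles
water,O
ammonia,N
hydrogen sulfide,S
hydrogen peroxide,OO
carbon dioxide,O=C=O
methane,C
ethane,CC
propane,CCC
butane,CCCC
isobutane,CC(C)C
pentane,CCCCC
hexane,CCCCCC
heptane,CCCCCCC
octane,CCCCCCCC
ethene,C=C
ethylene,C=C
propene,CC=C
ethyne,C#C
acetylene,C#C
cyclopropane,C1CC1
cyclobutane,C1CCC1
cyclopentane,C1CCCC1
cyclohexane,C1CCCCC1
methanol,CO
ethanol,CCO
propanol,CCCO
isopropanol,CC(O)C
butanol,CCCCO
ethylene glycol,OCCO
glycerol,OCC(O)CO
dimethyl ether,COC
diethyl ether,CCOCC
formaldehyde,C=O
acetaldehyde,CC=O
acetone,CC(=O)C
formic acid,C(=O)O
acetic acid,CC(=O)O
lactic acid,CC(O)C(=O)O
citric acid,OC(=O)CC(O)(C(=O)O)CC(=O)O
glycine,NCC(=O)O
alanine,CC(N)C(=O)O
urea,NC(=O)N
methylamine,CN
acetonitrile,CC#N
nitromethane,C[N+](=O)[O-]
chloroform,ClC(Cl)Cl
dichloromethane,ClCCl
benzene,c1ccccc1
toluene,Cc1ccccc1
phenol,Oc1ccccc1
aniline,Nc1ccccc1
chlorobenzene,Clc1ccccc1
styrene,C=Cc1ccccc1
pyridine,c1ccncc1
pyrrole,c1cc[nH]c1
furan,c1ccoc1
thiophene,c1ccsc1
naphthalene,c1ccc2ccccc2c1
glucose,OCC1OC(O)C(O)C(O)C1O
aspirin,CC(=O)Oc1ccccc1C(=O)O
paracetamol,CC(=O)Nc1ccc(O)cc1
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C
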