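# Reference standards of the injection's quality-control panel, one
# "SMILES<TAB>id<TAB>name" record per line.
C12CC3(O)C1(COC(=O)c4ccc(O)cc4)C5OC3(C)CC2(OC6OC(CO)C(O)C(O)C6O)O5	oxypaeoniflorin	oxypaeoniflorin
CCCC=C1OC(=O)C2=C1CCC(O)C2O	senkyunolide_I	senkyunolide I
C1=CC(=C(C=C1C2=CC(=O)C3=C(C=C(C=C3O2)O)O)O)O	luteolin	luteolin
CC1=COC2=C1C(=O)C(=O)C3=C2C=CC4=C3CCCC4(C)C	tanshinone_IIA	tanshinone IIA
C1=CC=C(C=C1)C2=CC(=O)C3=C(C(=C(C=C3O2)O)O)O	baicalein	baicalein
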