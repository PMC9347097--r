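id,smiles
D1,CC(=O)Oc1ccccc1C(=O)O
D2,CN1CCC[C@@H]1c1cccnc1
D3,Clc1ccc(Br)cc1
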