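drug_id	smiles
drug_ethanol	CCO
drug_benzene	c1ccccc1
drug_aspirin	CC(=O)Oc1ccccc1C(=O)O
drug_caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C
drug_ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O
drug_paracetamol	CC(=O)Nc1ccc(O)cc1
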