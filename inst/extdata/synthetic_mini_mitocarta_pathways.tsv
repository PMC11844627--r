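MitoPathway	MitoPathways Hierarchy	Genes
OXPHOS	OXPHOS	MT-ND1, MT-ND2, NDUFA1, NDUFB1, NDUFS1, NDUFAF1, MT-CO1, MT-CO2, COX4I1, COX5A, ATP5F1A
Complex I	OXPHOS > Complex I	MT-ND1, MT-ND2, NDUFA1, NDUFB1, NDUFS1, NDUFAF1
CI subunits	OXPHOS > Complex I > CI subunits	MT-ND1, MT-ND2, NDUFA1, NDUFB1, NDUFS1
Complex IV	OXPHOS > Complex IV	MT-CO1, MT-CO2, COX4I1, COX5A
Metabolism	Metabolism	ACADM, ACADVL, CPT1A, CPT2, HADHA, ETFDH, GLUD1, GLS, OAT, ALDH18A1, MYG1
Fatty acid oxidation	Metabolism > Fatty acid oxidation	ACADM, ACADVL, CPT1A, CPT2, HADHA, ETFDH
Amino acid metabolism	Metabolism > Amino acid metabolism	GLUD1, GLS, OAT, ALDH18A1
Glutamate metabolism	Metabolism > Amino acid metabolism > Glutamate metabolism	GLUD1, GLS
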