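Symbol
MT-ND1
MT-ND2
NDUFA1
NDUFB1
NDUFS1
NDUFAF1
MT-CO1
MT-CO2
COX4I1
COX5A
ATP5F1A
ACADM
ACADVL
CPT1A
CPT2
HADHA
ETFDH
GLUD1
GLS
OAT
ALDH18A1
MYG1
SFXN5
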