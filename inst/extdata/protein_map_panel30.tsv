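protein	gene_symbol
CD3	CD3D
CD3	CD3G
CD3	CD3E
HLA-DR	HLA-DRA
HLA-DR	HLA-DRB1
HLA-DR	HLA-DRB5
CD16	FCGR1A
CD16	FCGR2A
CD16	FCGR3A
CD16	FCGR1B
CD16	FCGR2B
CD16	FCGR3B
CD4	CD4
CD8	CD8A
CD14	CD14
CD19	CD19
CD25	IL2RA
CD27	CD27
CD28	CD28
CD34	CD34
CD38	CD38
CD45RA	PTPRC
CD56	NCAM1
CD57	B3GAT1
CD69	CD69
CD79b	CD79B
CD123	IL3RA
CD127	IL7R
CD137	TNFRSF9
CD161	KLRB1
CD197	CCR7
CD274	CD274
CD278	ICOS
CD335	NCR1
PD1	PDCD1
TIGIT	TIGIT
HLA_ABC	HLA-A
TCRgd	TRDC
IgM	IGHM
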