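dataset	prof	netsurfp	spider3	oligomeric_state
Aminoglycoside kinase	0.66	0.75	0.69	Dimer
BRCA1 RING domain	0.45	0.62	0.66	Monomer
CcdB	0.71	0.75	0.74	Dimer
Gal4 (DBD)	0.73	0.77	0.66	Tetramer
GB1 (IgG-binding domain)	0.67	0.52	0.64	Monomer
Hsp90 (ATPase domain)	0.56	0.64	0.59	Tetramer
NUDT15	0.55	0.63	0.62	Dimer
Pab1 (RRM domain)	0.75	0.81	0.77	Dimer
PSD (pdz3 domain)	0.74	0.81	0.61	Dimer
TEM1 beta-lactamase	0.74	0.81	0.79	Monomer
Ubiquitin	0.74	0.84	0.73	Monomer
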