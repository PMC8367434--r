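family_id	max_evalue	set
DSYB	1e-30	core
DsyB	1e-67	core
MmtN	1e-98	core
DmdA	1e-130	core
DmdB	1e-75	core
DmdC	1e-100	core
DmdD	1e-30	core
AcuH	1e-56	core
DddD	1e-97	core
DddK	1e-35	core
DddL	1e-33	core
DddP	1e-83	core
DddQ	1e-20	core
DddW	1e-49	core
DddY	1e-64	core
Alma1	1e-26	core
DmoA	1e-34	core
MddA	1e-30	core
MTO	1e-20	core
DorA	1e-30	core
DdhA	1e-30	supplementary
DdhB	1e-30	supplementary
DdhC	1e-30	supplementary
Tmm	1e-30	supplementary
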