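pathway_id	display_name	cycle	route_index	component_index	families
ASR	Assimilatory sulfite reduction (sulfite->sulfide)	sulfur	1	1	K00392
ASR	Assimilatory sulfite reduction (sulfite->sulfide)	sulfur	2	1	K00380
ASR	Assimilatory sulfite reduction (sulfite->sulfide)	sulfur	2	2	K00381
DNRA	Dissimilatory nitrite reduction to ammonia	nitrogen	1	1	K00362
DNRA	Dissimilatory nitrite reduction to ammonia	nitrogen	1	2	K00363
DNRA	Dissimilatory nitrite reduction to ammonia	nitrogen	2	1	K03385
DNRA	Dissimilatory nitrite reduction to ammonia	nitrogen	2	2	K15876
thiosulfate_disproportionation	Thiosulfate disproportionation (thiosulfate->sulfide+sulfite)	sulfur	1	1	phsA
thiosulfate_disproportionation	Thiosulfate disproportionation (thiosulfate->sulfide+sulfite)	sulfur	1	2	phsB
thiosulfate_disproportionation	Thiosulfate disproportionation (thiosulfate->sulfide+sulfite)	sulfur	1	3	phsC
dmsp_biosynthesis	DMSP biosynthesis (methionine->DMSP)	DMSP	1	1	DSYB,DsyB,MmtN
dmsp_demethylation	DMSP demethylation (DMSP->MMPA)	DMSP	1	1	DmdA
mmpa_to_mesh	MMPA degradation (MMPA->MeSH)	DMSP	1	1	DmdB
mmpa_to_mesh	MMPA degradation (MMPA->MeSH)	DMSP	1	2	DmdC
mmpa_to_mesh	MMPA degradation (MMPA->MeSH)	DMSP	1	3	DmdD
mmpa_to_mesh	MMPA degradation (MMPA->MeSH)	DMSP	2	1	AcuH
dmsp_cleavage	DMSP cleavage (DMSP->DMS)	DMSP	1	1	DddD,DddK,DddL,DddP,DddQ,DddW,DddY,Alma1
dms_to_mesh	DMS oxidation (DMS->MeSH)	DMSP	1	1	DmoA
dms_to_dmso	DMS oxidation (DMS->DMSO)	DMSP	1	1	DdhA
dms_to_dmso	DMS oxidation (DMS->DMSO)	DMSP	1	2	DdhB
dms_to_dmso	DMS oxidation (DMS->DMSO)	DMSP	1	3	DdhC
dms_to_dmso	DMS oxidation (DMS->DMSO)	DMSP	2	1	Tmm
dmso_to_dms	DMSO reduction (DMSO->DMS)	DMSP	1	1	DorA
mesh_to_dms	MddA pathway (MeSH->DMS)	DMSP	1	1	MddA
mesh_oxidation	MeSH oxidation (MeSH->formaldehyde)	DMSP	1	1	MTO
sulfo_EMP	Sulfoquinovose degradation, sulfo-EMP pathway	sulfur	1	1	K18479
sulfo_EMP	Sulfoquinovose degradation, sulfo-EMP pathway	sulfur	1	2	K18478
sulfo_EMP	Sulfoquinovose degradation, sulfo-EMP pathway	sulfur	1	3	K01671
sulfo_EMP	Sulfoquinovose degradation, sulfo-EMP pathway	sulfur	1	4	K08318
sulfo_ED	Sulfoquinovose degradation, sulfo-ED pathway	sulfur	1	1	SQDH
sulfo_ED	Sulfoquinovose degradation, sulfo-ED pathway	sulfur	1	2	SGLL
sulfo_ED	Sulfoquinovose degradation, sulfo-ED pathway	sulfur	1	3	SGDT
sulfo_ED	Sulfoquinovose degradation, sulfo-ED pathway	sulfur	1	4	KDSGA
sulfo_ED	Sulfoquinovose degradation, sulfo-ED pathway	sulfur	1	5	SLADH
SFT	Sulfoquinovose degradation, SF-transaldolase pathway	sulfur	1	1	K18479
SFT	Sulfoquinovose degradation, SF-transaldolase pathway	sulfur	1	2	SFTA
SFT	Sulfoquinovose degradation, SF-transaldolase pathway	sulfur	1	3	SLADH
isoprene_degradation	Isoprene degradation (isoprene monooxygenase)	carbon	1	1	IsoA
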