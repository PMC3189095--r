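pair	fwd_name	rev_name	enzyme	component
pSC101QC	pSC101QC F1	pSC101QC R1	BglII	pSC101 origin
CmQC	CmQC F1	CmQC R1	EcoRI	chloramphenicol resistance gene
KanQC	KanQC F1	KanQC R1	BglII	kanamycin resistance gene promoter
pProS	pProS F2	pProS R2	EcoRI	Salmonella PprpB promoter system
pProE	pProE F2	pProE R2	XhoI	E. coli PprpB promoter system
pBAD	pBAD F2	pBAD R2	BamHI	PBAD promoter system
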