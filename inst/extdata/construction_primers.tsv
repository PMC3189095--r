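name	sequence	description
pSC101QC F1	gaatttacagatacccagatcAcccgggaaaagg	to remove BglII site on pSC101
pSC101QC R1	ccttttcccgggTgatctgggtatctgtaaattc	to remove BglII site on pSC101
pBBR1 F1	gatcaCCTAGGctacagccgatagtctggaacagcgc	for pBBR1 origin with AvrII
pBBR1 mut R1	ccggcaccgtgtTggcctacgtggtc	to increase copy number of pBBR1
pBBR1 mut F1	gaccacgtaggccAacacggtgccgg	to increase copy number of pBBR1
pBBR1 R2	agatcaACTAGTgcctccggcctgcggcctgcgcgcttcg	for pBBR1 origin with SpeI
CmQC F1	ctttcattgccatacgAaattccggatgagcattc	to remove EcoRI site on CmR
CmQC R1	gaatgctcatccggaattTcgtatggcaatgaaag	to remove EcoRI site on CmR
KanQC F1	cctgtctcttgatcagatcAtgatcccctgc	to remove BglII site on KmR
KanQC R1	gcaggggatcaTgatctgatcaagagacagg	to remove BglII site on KmR
RFP F1	aaaAGATCTtttaagaaggagatatacatATGgcgagtagcgaagacgttatc	for rfp with BglII
RFP R1	CTCGAGtttGGATCCttaagcaccggtggagtgacg	for rfp with BamHI and XhoI
Term F1	gtgcttaaGGATCCaaaCTCGAGtaaggatctccaggcatcaaataaaacg	for double terminator with BamHI and XhoI
Term R1	gatcaCCTAGGtataaacgcagaaaggcccacccgaagg	for double terminator with AvrII
pTrc F1	agatcaGACGTCgacaccatcgaatggtgcaaaacc	for Ptrc with AatII
placUV5 R1	tatctccttcttaaaAGATCTtttGAATTCtgaaattgttatccgctcacaattc	for Ptrc, PlacUV5, and PT7 with EcoRI and BglII
pTet F1	agatcaGACGTCttaagacccactttcacatttaagttg	for Ptet with AatII
pTet R1	tatctccttcttaaaAGATCTtttGAATTCttttctctatcactgatagggagtgg	for Ptet with EcoRI and BglII
pProS F1	agatcaGACGTCttaattacccgactggtctttggcac	for Salmonella based PprpB with AatII
pProS R2	gggatatcagcctggaattTgatcatctggcgacc	to remove EcoRI site
pProS F2	ggtcgccagatgatcAaattccaggctgatatccc	to remove EcoRI site
pProS R1	tatctccttcttaaaAGATCTtttGAATTCcatgttagtaaattgttattcaag	for Salmonella based PprpB with EcoRI and BglII
pProE F1	agatcaGACGTCtcagcttttcagccgccgccagaac	for E. coli based PprpB with AatII
pProE R2	gtttcgcgatatcagcctTgagtttgatcacctgg	to remove XhoI site
pProE F2	ccaggtgatcaaactcAaggctgatatcgcgaaac	to remove XhoI site
pProE R1	tatctccttcttaaaAGATCTtttGAATTCttgttatcaacttgttatttgcgttg	for E. coli based PprpB with EcoRI and BglII
lacUV5 F1	agatcaGACGTCggtgcctaatgagtgagctaacttacattaattgc	for PlacUV5 with AatII
PLlacO-1 F1	agatcaGACGTCggtgcctaatgagtgagctaacttacattaattg	for lacI with AatII
PLlacO-1 R2	aatgtcaattgttatccgctcacaattctcgatcctctacgccggacg	for lacI
PLlacO-1 F2	cgtccggcgtagaggatcgagaattgtgagcggataacaattgacatt	for PLlacO-1
PLlacO-1 R1	tatctccttcttaaaAGATCTtttGAATTCggtcagtgcgtcctgctgatgtg	for PLlacO-1 with EcoRI and BglII
pT7 F1	agatcaGACGTCctcactgcccgctttccagtc	for PT7 with AatII
pBAD F1	agatcaGACGTCttatgacaacttgacggctacatcattcac	for PBAD with AatII
pBAD R2	gataaaaagcgtcaggtagAatccgctaatcttatgg	to remove BamHI site
pBAD F2	ccataagattagcggatTctacctgacgctttttatc	to remove BamHI site
pBAD R1	tatctccttcttaaaAGATCTtttGAATTCccaaaaaaacgggtatggagaaacag	for PBAD with EcoRI and BglII
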