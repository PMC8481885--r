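mrna	mirna	lncrna
PTEN	hsa-miR-106b	FAM13A-AS1
PTEN	hsa-miR-23a	FAM13A-AS1
PTEN	hsa-miR-25	FAM13A-AS1
PTEN	hsa-miR-93	FAM13A-AS1
PTEN	hsa-miR-106b	LINC00173
PTEN	hsa-miR-181a	LINC00173
PTEN	hsa-miR-181b	LINC00173
PTEN	hsa-miR-181c	LINC00173
PTEN	hsa-miR-23a	LINC00173
PTEN	hsa-miR-93	LINC00173
PTEN	hsa-miR-181a	OIP5-AS1
PTEN	hsa-miR-181b	OIP5-AS1
PTEN	hsa-miR-181c	OIP5-AS1
PTEN	hsa-miR-25	OIP5-AS1
PTEN	hsa-miR-93	OIP5-AS1
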