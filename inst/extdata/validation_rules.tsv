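gene_family	min_score	max_evalue	title_keywords	allowed_taxa	motif_patterns	notes
mcrA	NA	1e-5	methyl coenzyme M reductase	NA	NA	PF02249; title keyword confirms identity against the NCBI nr best hit
pmoA	NA	1e-5	methane monooxygenase	f__Methylomonadaceae|f__Beijerinckiaceae|f__Methylococcaceae|f__Methylocystaceae	NA	homologous to AmoA; restricted to known methanotrophic families (allow-list user-replaceable)
mmoX	NA	1e-5	methane monooxygenase	NA	NA	soluble methane monooxygenase alpha subunit
hgcA	NA	1e-5	NA	NA	N[VI]WCA[AG]GK	cap-helix conserved motif
hgcB	NA	1e-5	NA	NA	C[MI]ECGA	ferredoxin twin-cysteine conserved motif
merB	NA	1e-5	NA	NA	C[LIVM]ACG|SCPTC|GD[LF]D	SYNTHETIC stand-in residue-context signatures (two Cys, one Asp); the published validation cites signature residues without printing them - replace with curated patterns for real data
dsrA	392.9	NA	NA	NA	NA	TIGR02064.1 sequence bit-score cutoff
mbnT	223.5	NA	NA	g__Methylomicrobium|g__Methylocystis|g__Methylosinus	NA	TIGR01783 cutoff; conservative genus allow-list of demethylating methanotrophs
iron_reduction	NA	1e-5	NA	NA	NA	FeGenie-style iron-reduction gene set; per-gene domain E-value cutoffs collapse to a single default here
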