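# Nearest-neighbor free-energy parameters, DNA, 37 C, kcal/mol.
# Provenance: SantaLucia unified DNA parameters as compiled in the
# Mathews 2004 DNA folding set. Watson-Crick stacks only.
# stack code = outer 5' base, inner 5' base, inner 3' base, outer 3' base
# version: dna-mathews2004-wc-1.0
record	key1	key2	dg_kcal_mol
stack	CCGG		-1.80
stack	CGCG		-2.20
stack	CATG		-1.50
stack	CTAG		-1.30
stack	GCGC		-2.20
stack	GGCC		-1.80
stack	GATC		-1.30
stack	GTAC		-1.40
stack	ACGT		-1.40
stack	AGCT		-1.30
stack	AATT		-1.00
stack	ATAT		-0.90
stack	TCGA		-1.30
stack	TGCA		-1.50
stack	TATA		-0.60
stack	TTAA		-1.00
mismatch_hairpin	CG	AA	-1.00
mismatch_hairpin	CG	AC	-0.80
mismatch_hairpin	CG	AG	-0.90
mismatch_hairpin	CG	AT	0.00
mismatch_hairpin	CG	CA	-0.80
mismatch_hairpin	CG	CC	-0.50
mismatch_hairpin	CG	CG	0.00
mismatch_hairpin	CG	CT	-0.70
mismatch_hairpin	CG	GA	-1.00
mismatch_hairpin	CG	GC	0.00
mismatch_hairpin	CG	GG	-0.90
mismatch_hairpin	CG	GT	-1.00
mismatch_hairpin	CG	TA	0.00
mismatch_hairpin	CG	TC	-0.60
mismatch_hairpin	CG	TG	-0.90
mismatch_hairpin	CG	TT	-0.90
mismatch_hairpin	GC	AA	-1.00
mismatch_hairpin	GC	AC	-0.70
mismatch_hairpin	GC	AG	-0.80
mismatch_hairpin	GC	AT	0.00
mismatch_hairpin	GC	CA	-1.00
mismatch_hairpin	GC	CC	-0.60
mismatch_hairpin	GC	CG	0.00
mismatch_hairpin	GC	CT	-0.70
mismatch_hairpin	GC	GA	-1.00
mismatch_hairpin	GC	GC	0.00
mismatch_hairpin	GC	GG	-1.00
mismatch_hairpin	GC	GT	-0.80
mismatch_hairpin	GC	TA	0.00
mismatch_hairpin	GC	TC	-0.60
mismatch_hairpin	GC	TG	-0.90
mismatch_hairpin	GC	TT	-0.90
mismatch_hairpin	AT	AA	-0.70
mismatch_hairpin	AT	AC	-0.30
mismatch_hairpin	AT	AG	-0.50
mismatch_hairpin	AT	AT	0.00
mismatch_hairpin	AT	CA	-0.60
mismatch_hairpin	AT	CC	-0.20
mismatch_hairpin	AT	CG	0.00
mismatch_hairpin	AT	CT	-0.30
mismatch_hairpin	AT	GA	-0.60
mismatch_hairpin	AT	GC	0.00
mismatch_hairpin	AT	GG	-0.40
mismatch_hairpin	AT	GT	-0.50
mismatch_hairpin	AT	TA	0.00
mismatch_hairpin	AT	TC	-0.30
mismatch_hairpin	AT	TG	-0.50
mismatch_hairpin	AT	TT	-0.40
mismatch_hairpin	TA	AA	-0.60
mismatch_hairpin	TA	AC	-0.40
mismatch_hairpin	TA	AG	-0.50
mismatch_hairpin	TA	AT	0.00
mismatch_hairpin	TA	CA	-0.50
mismatch_hairpin	TA	CC	-0.20
mismatch_hairpin	TA	CG	0.00
mismatch_hairpin	TA	CT	-0.50
mismatch_hairpin	TA	GA	-0.60
mismatch_hairpin	TA	GC	-0.00
mismatch_hairpin	TA	GG	-0.40
mismatch_hairpin	TA	GT	-0.50
mismatch_hairpin	TA	TA	0.00
mismatch_hairpin	TA	TC	-0.30
mismatch_hairpin	TA	TG	-0.60
mismatch_hairpin	TA	TT	-0.30
hairpin_init	3		3.40
hairpin_init	4		3.40
hairpin_init	5		3.50
hairpin_init	6		4.20
hairpin_init	7		4.20
hairpin_init	8		4.20
hairpin_init	9		4.30
hairpin_init	10		4.40
hairpin_init	11		4.50
hairpin_init	12		4.60
hairpin_init	13		4.70
hairpin_init	14		4.80
hairpin_init	15		5.00
hairpin_init	16		5.10
hairpin_init	17		5.20
hairpin_init	18		5.30
hairpin_init	19		5.40
hairpin_init	20		5.50
hairpin_init	21		5.60
hairpin_init	22		5.70
hairpin_init	23		5.80
hairpin_init	24		5.90
hairpin_init	25		6.00
hairpin_init	26		6.10
hairpin_init	27		6.20
hairpin_init	28		6.30
hairpin_init	29		6.40
hairpin_init	30		6.50
terminal_au			0.00
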