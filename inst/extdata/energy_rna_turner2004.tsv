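# Nearest-neighbor free-energy parameters, RNA, 37 C, kcal/mol.
# Provenance: Turner 2004 RNA folding parameters (Mathews et al. 2004;
# Turner & Mathews NAR 2010 compilation). Watson-Crick stacks only.
# stack code = outer 5' base, inner 5' base, inner 3' base, outer 3' base
# (helix read 5'->3' on the top strand).
# version: turner2004-wc-1.0
record	key1	key2	dg_kcal_mol
stack	CCGG		-3.30
stack	CGCG		-2.40
stack	CAUG		-2.10
stack	CUAG		-2.10
stack	GCGC		-3.40
stack	GGCC		-3.30
stack	GAUC		-2.40
stack	GUAC		-2.20
stack	ACGU		-2.20
stack	AGCU		-2.10
stack	AAUU		-0.90
stack	AUAU		-1.10
stack	UCGA		-2.40
stack	UGCA		-2.10
stack	UAUA		-1.30
stack	UUAA		-0.90
mismatch_hairpin	CG	AA	-1.50
mismatch_hairpin	CG	AC	-1.50
mismatch_hairpin	CG	AG	-1.40
mismatch_hairpin	CG	AU	-1.50
mismatch_hairpin	CG	CA	-1.00
mismatch_hairpin	CG	CC	-1.10
mismatch_hairpin	CG	CG	-1.00
mismatch_hairpin	CG	CU	-0.80
mismatch_hairpin	CG	GA	-2.30
mismatch_hairpin	CG	GC	-1.50
mismatch_hairpin	CG	GG	-2.40
mismatch_hairpin	CG	GU	-1.50
mismatch_hairpin	CG	UA	-1.00
mismatch_hairpin	CG	UC	-1.40
mismatch_hairpin	CG	UG	-1.00
mismatch_hairpin	CG	UU	-2.10
mismatch_hairpin	GC	AA	-1.10
mismatch_hairpin	GC	AC	-1.50
mismatch_hairpin	GC	AG	-1.30
mismatch_hairpin	GC	AU	-1.50
mismatch_hairpin	GC	CA	-1.10
mismatch_hairpin	GC	CC	-0.70
mismatch_hairpin	GC	CG	-1.10
mismatch_hairpin	GC	CU	-0.50
mismatch_hairpin	GC	GA	-2.50
mismatch_hairpin	GC	GC	-1.50
mismatch_hairpin	GC	GG	-2.20
mismatch_hairpin	GC	GU	-1.50
mismatch_hairpin	GC	UA	-1.10
mismatch_hairpin	GC	UC	-1.00
mismatch_hairpin	GC	UG	-1.10
mismatch_hairpin	GC	UU	-1.60
mismatch_hairpin	AU	AA	-0.30
mismatch_hairpin	AU	AC	-0.50
mismatch_hairpin	AU	AG	-0.30
mismatch_hairpin	AU	AU	-0.50
mismatch_hairpin	AU	CA	-0.10
mismatch_hairpin	AU	CC	-0.20
mismatch_hairpin	AU	CG	-0.10
mismatch_hairpin	AU	CU	-0.20
mismatch_hairpin	AU	GA	-1.20
mismatch_hairpin	AU	GC	-0.50
mismatch_hairpin	AU	GG	-1.10
mismatch_hairpin	AU	GU	-0.50
mismatch_hairpin	AU	UA	-0.10
mismatch_hairpin	AU	UC	-0.30
mismatch_hairpin	AU	UG	-0.10
mismatch_hairpin	AU	UU	-1.20
mismatch_hairpin	UA	AA	-0.50
mismatch_hairpin	UA	AC	-0.30
mismatch_hairpin	UA	AG	-0.50
mismatch_hairpin	UA	AU	-0.30
mismatch_hairpin	UA	CA	-0.20
mismatch_hairpin	UA	CC	-0.10
mismatch_hairpin	UA	CG	-0.20
mismatch_hairpin	UA	CU	0.00
mismatch_hairpin	UA	GA	-1.50
mismatch_hairpin	UA	GC	-0.30
mismatch_hairpin	UA	GG	-1.50
mismatch_hairpin	UA	GU	-0.30
mismatch_hairpin	UA	UA	-0.20
mismatch_hairpin	UA	UC	-0.10
mismatch_hairpin	UA	UG	-0.20
mismatch_hairpin	UA	UU	-0.90
hairpin_init	3		5.40
hairpin_init	4		5.60
hairpin_init	5		5.70
hairpin_init	6		5.40
hairpin_init	7		6.00
hairpin_init	8		5.50
hairpin_init	9		6.40
hairpin_init	10		6.50
hairpin_init	11		6.60
hairpin_init	12		6.70
hairpin_init	13		6.80
hairpin_init	14		6.90
hairpin_init	15		6.90
hairpin_init	16		7.00
hairpin_init	17		7.10
hairpin_init	18		7.10
hairpin_init	19		7.20
hairpin_init	20		7.20
hairpin_init	21		7.30
hairpin_init	22		7.30
hairpin_init	23		7.40
hairpin_init	24		7.40
hairpin_init	25		7.50
hairpin_init	26		7.50
hairpin_init	27		7.50
hairpin_init	28		7.60
hairpin_init	29		7.60
hairpin_init	30		7.70
terminal_au			0.50
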