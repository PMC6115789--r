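# RNA nearest-neighbor free-energy parameters, dG at 37 C, kcal/mol (v1).
# record=stack: key1 = 5' outer pair, key2 = inner pair read 3'->5' (reversed);
#   the table is symmetric under that encoding.
# record=bulge|internal|hairpin: key1 = loop size (nt); sizes beyond the table
#   are extrapolated as dg(max) + lxc * ln(size/max).
# record=misc: key1 = scalar name (duplex_init, terminal_au, ml_close, ml_branch,
#   ml_unpaired, ninio_per_nt, ninio_max, max_loop, lxc).
record	key1	key2	dg
stack	CG	CG	-2.4
stack	CG	GC	-3.3
stack	CG	GU	-2.1
stack	CG	UG	-1.4
stack	CG	AU	-2.1
stack	CG	UA	-2.1
stack	GC	CG	-3.3
stack	GC	GC	-3.4
stack	GC	GU	-2.5
stack	GC	UG	-1.5
stack	GC	AU	-2.2
stack	GC	UA	-2.4
stack	GU	CG	-2.1
stack	GU	GC	-2.5
stack	GU	GU	1.3
stack	GU	UG	-0.5
stack	GU	AU	-1.4
stack	GU	UA	-1.3
stack	UG	CG	-1.4
stack	UG	GC	-1.5
stack	UG	GU	-0.5
stack	UG	UG	0.3
stack	UG	AU	-0.6
stack	UG	UA	-1
stack	AU	CG	-2.1
stack	AU	GC	-2.2
stack	AU	GU	-1.4
stack	AU	UG	-0.6
stack	AU	AU	-1.1
stack	AU	UA	-0.9
stack	UA	CG	-2.1
stack	UA	GC	-2.4
stack	UA	GU	-1.3
stack	UA	UG	-1
stack	UA	AU	-0.9
stack	UA	UA	-1.3
bulge	1		3.8
bulge	2		2.8
bulge	3		3.2
bulge	4		3.6
bulge	5		4
bulge	6		4.4
bulge	7		4.6
bulge	8		4.7
bulge	9		4.8
bulge	10		4.9
bulge	11		5
bulge	12		5.1
bulge	13		5.2
bulge	14		5.3
bulge	15		5.4
bulge	16		5.4
bulge	17		5.5
bulge	18		5.5
bulge	19		5.6
bulge	20		5.7
bulge	21		5.7
bulge	22		5.8
bulge	23		5.8
bulge	24		5.8
bulge	25		5.9
bulge	26		5.9
bulge	27		6
bulge	28		6
bulge	29		6
bulge	30		6.1
internal	2		1
internal	3		1
internal	4		1.1
internal	5		2
internal	6		2
internal	7		2.1
internal	8		2.3
internal	9		2.4
internal	10		2.5
internal	11		2.6
internal	12		2.7
internal	13		2.8
internal	14		2.9
internal	15		2.9
internal	16		3
internal	17		3.1
internal	18		3.1
internal	19		3.2
internal	20		3.3
internal	21		3.3
internal	22		3.4
internal	23		3.4
internal	24		3.5
internal	25		3.5
internal	26		3.5
internal	27		3.6
internal	28		3.6
internal	29		3.7
internal	30		3.7
hairpin	3		5.4
hairpin	4		5.6
hairpin	5		5.7
hairpin	6		5.4
hairpin	7		6
hairpin	8		5.5
hairpin	9		6.4
hairpin	10		6.5
hairpin	11		6.6
hairpin	12		6.7
hairpin	13		6.8
hairpin	14		6.9
hairpin	15		6.9
hairpin	16		7
hairpin	17		7.1
hairpin	18		7.1
hairpin	19		7.2
hairpin	20		7.2
hairpin	21		7.3
hairpin	22		7.3
hairpin	23		7.4
hairpin	24		7.4
hairpin	25		7.5
hairpin	26		7.5
hairpin	27		7.5
hairpin	28		7.6
hairpin	29		7.6
hairpin	30		7.7
misc	duplex_init		4.1
misc	terminal_au		0.5
misc	ml_close		9.3
misc	ml_branch		-0.9
misc	ml_unpaired		0
misc	ninio_per_nt		0.6
misc	ninio_max		3
misc	max_loop		30
misc	lxc		1.07856
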