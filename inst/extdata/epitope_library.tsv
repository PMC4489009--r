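name	sequence	class	note
DQ2.5-glia-α1a	PFPQPQLPY	alpha	CD T-cell epitope
DQ2.5-glia-α1b	PYPQPQLPY	alpha	CD T-cell epitope
DQ2.5-glia-α2	PQPQLPYPQ	alpha	CD T-cell epitope
DQ2.5-glia-α3	FRPQQPYPQ	alpha	CD T-cell epitope
DQ8-glia-α1	QGSFQPSQQ	alpha	CD T-cell epitope; also nominated DQ8.5-glia-α1
19-residue-peptide	LGQQQPFPPQQPYPQPQPF	alpha	immunoreactive peptide, N-terminal repetitive domain
12-residue-peptide	LGQGSFRPSQQN	alpha	immunoreactive peptide, unique domain II
DQ2.5-glia-γ1	PQQSFPQQQ	gamma	CD T-cell epitope
DQ2.5-glia-γ2	IQPQQPAQL	gamma	CD T-cell epitope
DQ2.5-glia-γ3	QQPQQPYPQ	gamma	CD T-cell epitope
DQ2.5-glia-γ4a	SQPQQQFPQ	gamma	CD T-cell epitope
DQ2.5-glia-γ4b	PQPQQQFPQ	gamma	CD T-cell epitope
DQ2.5-glia-γ4c	QQPQQPFPQ	gamma	CD T-cell epitope
DQ2.5-glia-γ4d	PQPQQPFCQ	gamma	CD T-cell epitope
DQ2.5-glia-γ5	QQPFPQQPQ	gamma	CD T-cell epitope
DQ8-glia-γ1a	QQPQQPFPQ	gamma	same sequence as DQ2.5-glia-γ4c; deamidation context differs
DQ8-glia-γ1b	QQPQQPYPQ	gamma	same sequence as DQ2.5-glia-γ3; deamidation context differs
DQ8.5-glia-γ1	PQQSFPQQQ	gamma	same sequence as DQ2.5-glia-γ1; deamidation context differs
DQ2.5-glia-ω1	PFPQPQQPF	omega	CD T-cell epitope
DQ2.5-glia-ω2	PQPQQPFPW	omega	CD T-cell epitope
heptapeptide-QQIPQQQ	QQIPQQQ	omega	immunoreactive heptapeptide
heptapeptide-QQLPQQQ	QQLPQQQ	omega	immunoreactive heptapeptide
heptapeptide-QQFPQQQ	QQFPQQQ	omega	immunoreactive heptapeptide
heptapeptide-QQSPQQQ	QQSPQQQ	omega	immunoreactive heptapeptide
heptapeptide-QQSPEQQ	QQSPEQQ	omega	immunoreactive heptapeptide
heptapeptide-QQYPQQQ	QQYPQQQ	omega	immunoreactive heptapeptide
heptapeptide-QSPEQQQ	QSPEQQQ	omega	immunoreactive heptapeptide
heptapeptide-YQQYPQQ	YQQYPQQ	omega	immunoreactive heptapeptide
heptapeptide-QQFHQQQ	QQFHQQQ	omega	immunoreactive heptapeptide
tetrapeptide-QQQP	QQQP	omega	immunoreactive tetrapeptide
tetrapeptide-PYPP	PYPP	omega	immunoreactive tetrapeptide
hexapeptide-QQPPQQ	QQPPQQ	omega	immunoreactive hexapeptide (introductory enumeration)
hexapeptide-QQFPQQ	QQFPQQ	omega	immunoreactive hexapeptide (reported in omega repetitive regions); retained alongside QQPPQQ
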