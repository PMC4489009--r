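---
title: "Methods: annotating gliadin gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating gliadin gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliadinR)
```

# The problem

Gliadins are the alcohol-soluble storage proteins of wheat grain,
subdivided into α-, γ- and ω-types. Each type forms a multigene family of
nearly identical members, roughly half of which are pseudogenes, and each
carries a distinctive structural grammar and a load of celiac-disease
(CD) epitopes. `gliadinR` implements the complete desk-side analysis of
such a family: ORF/pseudogene classification with mutational origins,
domain segmentation, epitope and motif content, theoretical
physicochemistry, RPKM expression classification over grain development,
and assignment of two-dimensional electrophoresis (2-DE) spots to genes.
A ground-truthed synthetic generator stands in for cloned sequence sets
so that every stage is testable end to end.

# ORF classification and stop-codon origins

A coding sequence is translated with the standard genetic code; internal
stops are rendered `*` so pseudogenes still obtain a conceptual
translation for downstream structural analysis. The catalogue convention
is that a fragment length excludes the terminal stop codon, so fragment
length equals exactly three times the predicted protein length for
full-ORF genes; sequences arriving with a terminal stop are trimmed with
a warning.

Because prolamins are extraordinarily glutamine-rich, pseudogenization is
dominated by one mutational mechanism: a C→T transition at the first
position of a glutamine codon (CAA→TAA, CAG→TAG) or, rarely, of a CGA
arginine codon (→TGA). `classify_stop_origin()` therefore labels a stop
as explained only when a *single* C→T change at codon position 1
reconstructs the aligned reference codon; anything else is
`unexplained`, and a gap in the aligned reference marks the stop
`frameshift-induced`.

The reference for each gene is chosen from the family's own full-ORF
panel by highest global nucleotide identity (ties: longer reference, then
lexicographic id). Identity for equal-length pairs is the exact
positional match fraction; unequal-length pairs are scored by global
alignment (match +1, mismatch −1, gap open −5, gap extend −1, all
configurable). Frameshifts are searched *only* when the reading frame is
actually broken (length ≢ 0 mod 3): a global alignment between two
distinct full-ORF relatives legitimately contains in-frame indels —
polyglutamine tract-length variation — and treating those as frameshifts
would misclassify active genes. Indel positions are reported at the first
affected reference base pair and left-normalized within homopolymer runs,
the same canonicalization used for variant calls, because gap placement
inside a run is otherwise arbitrary.

# Domain grammar

Domain coordinates are 1-based inclusive protein positions, and every
segmentation is a partition: domains are contiguous, ordered, and cover
residue 1 to the end, with empty domains permitted.

The signal peptide is a fixed-length prefix per type (20 residues for α
and γ, 19 for ω, overridable per gene). A fixed length was chosen over a
cleavage-site predictor deliberately: it is deterministic, testable, and
the only stated length in the family literature is the 20-residue γ
signal.

A polyglutamine tract is a maximal region that starts and ends with Q,
contains ≥ 80 % Q, and is at least 6 residues long; Q-runs separated by
≤ 2 non-Q residues merge when the merged region still satisfies the
fraction rule. These thresholds are this package's operationalization of
tract boundaries that alignment figures display but never define. For α
proteins the first tract after the signal is QI and the second QII
(leftmost-first, since QI precedes QII in every published structure);
the regions between and after become repetitive, UI, UII. An α protein
with fewer than two tracts keeps its label order with an empty QII and a
warning flag. For γ proteins the dominant (longest) tract is domain IV,
and the repetitive domain II is the maximal region covered ≥ 60 % by
PFPQ₁₋₂(PQQ)₁₋₂ unit matches; for ω proteins the repetitive region spans
all hepta/octapeptide-unit matches (including the degenerate QQQP-style
variants) and the flanks become the N- and C-terminal regions.

# Epitopes, motifs and classification rules

The CD epitope library ships as a versioned TSV
(`inst/extdata/epitope_library.tsv`): five α epitopes plus the
19-residue and 12-residue immunoreactive peptides, eleven γ epitopes,
and the ω epitopes with the immunoreactive hepta-, tetra- and
hexapeptides. Matching is exact — a hit is reported only at 100 %
sequence identity — and all overlapping occurrences are reported.
Library entries that share one amino-acid sequence and differ only in
deamidation context (γ4c/DQ8-glia-γ1a, γ3/DQ8-glia-γ1b, γ1/DQ8.5-glia-γ1)
collapse into a single hit carrying every name. Two ω hexapeptides
(QQPPQQ and QQFPQQ) are both retained because both appear in the
source literature's enumerations; the library note field records the
distinction rather than guessing which is canonical.
`near_miss_report()` enumerates windows at Hamming distance exactly one
from an epitope, the mechanism by which single SNPs disrupt epitopes
(e.g. a serine replacing the eighth proline).

Repeat units are counted greedily left-to-right without overlap (longest
unit first), matching how tandem units are tallied; an overlapping census
is available by flag, and the non-overlapping count can never exceed it.
The Q:P:F ratio reduces the three fractions (among Q+P+F residues) to
small integers by rounding eight times the fractions and dividing by
their GCD — 4:3:1 is the canonical ARQ/E-type ω composition.
`classify_omega()` uses the first three mature residues (ARQ/ARE, KEL,
SRL, TRQ) and falls back to the composition rule (each fraction within
0.05 of 4:3:1) to call ARQ/E-like variants. `classify_alpha_group()`
applies the published three-group rules over tract point-variants and
epitope content.

# Physicochemistry

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da); average rather than monoisotopic masses because gel-scale
MW values integrate over isotopologues (monoisotopic masses are computed
for digest peptides). The isoelectric point is found by bisection on pH
∈ [0, 14] to 0.005 pH units for the root of the Henderson–Hasselbalch
net charge; the charge is strictly decreasing in pH, so the root is
unique. The default pKa set is Bjellqvist (with residue-specific
terminal values, as in the ExPASy tools); an EMBOSS-style set is
selectable, and the set name is recorded in every output row. Because
published gel tables rarely state their pKa set, exact reproduction of
printed pI values is not promised; synthetic round-trips (spot within
3 kD / 0.5 pH of its source protein) validate the machinery instead.
MW/pI are computed on the full predicted protein by default (consistent
with catalogue-scale MW magnitudes), with a mature-protein option.

# Expression

RPKM is `C·10⁹ / (N·L)` with `C` the uniquely-mapped count, `N` the
library size and `L` the cloned fragment length in bp — fragment length
because quantification is against the cloned gene set, not a transcript
model. Replicates are averaged to stage means before any rule is applied
(median selectable). A gene is *expressed* when any grain-stage
(5–25 DPA) mean exceeds 1000 RPKM; flag-leaf samples never enter the
criterion, encoding endosperm specificity. A profile is *stable* when
the 10- and 20-DPA means both exceed 70 % of the 15-DPA mean. Threshold
and fraction are configuration keys with these defaults.

# Proteomics

Chymotryptic digestion cleaves C-terminal to F, Y, W, L and M, never
before proline; the extended (L/M-inclusive) specificity is the default
because observed gliadin peptides are frequently leucine-bounded, and
the high-specificity F/Y/W rule is a flag away. Peptides with up to two
missed cleavages and ≥ 5 residues are retained. Matching against the
predicted proteome is exact substring identity — spectral scoring is out
of scope by design. A spot is uniquely assigned when exactly one gene
owns a peptide found in no other protein; otherwise the spot keeps its
whole ambiguity group (the genes supported by every matching peptide),
and an ambiguous spot's volume is attributed to that group as a unit,
never split fractionally. Per-class totals simply sum every spot of a
gliadin class.

# The synthetic generator

The generator is the package's study design. Genes are built domain by
domain **at the codon level**, so nucleotide events are physically
plantable: polyglutamine tracts are CAA/CAG runs (60/40 weights, making
both CAA→TAA and CAG→TAG events possible), repetitive domains are drawn
from type-specific unit pools, epitopes are spliced in at configured
rates, and the unique domains carry the canonical cysteine skeletons
(α: 4 in UI + 2 in UII; γ: 6 in III + 2 in V; ω: none) plus a few
per-gene template substitutions that give every gene private chymotryptic
peptides. Defaults mirror the studied diploid family: 23 α / 3 γ / 2 ω
genes, a 12/28 pseudogene fraction, QI tracts of 9–33 residues (27–99 bp
of CAA/CAG), and about one frameshift per twelve pseudogenes.

Pseudogenes are generated as mutated copies of active family members —
the way storage-protein pseudogenes actually arise from recent
duplicates — with 1–3 planted C→T stops (biased toward QI, where such
stops are most frequent), occasionally a CGA→TGA event, or a single-base
deletion recorded at its left-normalized position. Every represented
type keeps at least one active gene so each pseudogene has a full-ORF
relative to be classified against. A configurable fraction of active α
genes are synonymous copies of an earlier member: identical proteins,
distinct CDS — the source of multi-gene 2-DE spots.

Expression counts are negative-binomial around RPKM-implied means with
the grain-filling shape (≈0 at 5 DPA, rise at 10, peak at 15, decline
through 25; leaf at background). Peak RPKM is log-normal around 15 000
(σ_log = 0.5), pseudogenes and leaf sit at background RPKM ≈ 2, and
library sizes are ≈ 21.8 million reads. The NB size parameter is 300
(CV ≈ 6 % per replicate): storage-protein transcripts at these depths are
measured with small relative error, and this choice makes the planted
stable/unstable profile flags (flat multipliers 0.85–0.95 versus peaked
0.5) recoverable rather than coin flips. Stable profiles are planted in
5/16 of active genes. Spots take their MW/pI from the member protein's
predicted values with small jitter (0.3 kD, 0.05 pH) and sample 6–12
peptides (≥ 7 residues) from the members' digests.

What the generator does *not* emulate: phylogenetic structure
(duplication trees, selection), read-level sequencing artifacts,
alignment ambiguity in count assignment, post-translational
modification, or the unexplained one-gene/many-spots phenomenon (it is
representable in the data model but never generated). Passing the
recovery suites therefore demonstrates the pipeline's correctness on
family structures of this shape, not robustness to assembly errors or
to real proteomic noise.

# Numerical choices and degenerate inputs

* Sizes used by the test and acceptance suites: recovery on a 200-gene
  family (the study's 23:3:2 type proportions scaled), expressed-set
  recovery over 100 expression replicates of a 28-gene family,
  spot-membership recovery over 10 simulated gels, and oracle equivalence
  on 100 (epitope scan), 50 (digest) and 20 (pI) random instances.
* All randomness flows from a single integer seed through
  stage-specific offsets; a fixed seed makes every output byte-identical,
  and the generator restores the caller's RNG state.
* Empty FASTA inputs produce an empty catalogue with a warning rather
  than an error; an α protein without two tracts is annotated with an
  empty QII and flagged; a spot whose peptides match nothing is reported
  `unassigned`; a fold summary refuses a zero minimum.
* Tie-breaks: equal polyQ tracts — leftmost is QI; equal-identity
  references — longer then lexicographic; repeat-unit greedy matching
  prefers the longest unit at each position.

# Known limitations

Signal peptides are fixed-length, not predicted; type inference uses
cysteine counts and repeat content and can return `unknown` for heavily
frameshifted conceptual translations (supplying a gene table with the
naming convention resolves types exactly); printed gel pI/MW values are
validated only through synthetic round-trips; and the published
catalogue row for one gene (864 bp with 287 predicted residues) violates
the 3 × arithmetic as printed — the table is transcribed faithfully and
the discrepancy is surfaced rather than silently corrected.
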