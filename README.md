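# gliadinR

Annotation and expression analysis of wheat **gliadin** gene families —
the proline/glutamine-rich prolamin seed-storage proteins (α-, γ- and
ω-type) that drive dough quality and carry the peptides recognized by
celiac-disease T cells.

Gliadin families are large, highly similar and riddled with pseudogenes,
which makes their annotation a repetitive, error-prone manual task. This
package turns that task into a reproducible pipeline. From a set of cloned
coding sequences it derives everything a family catalogue reports:

- **ORF status and mutation origin** — conceptual translation, internal
  stop detection, and classification of each stop's origin against the
  family's own full-ORF genes. In gliadins pseudogenization is dominated
  by a single C→T transition converting a glutamine codon into a stop
  (CAA→TAA, CAG→TAG, rarely CGA→TGA for arginine); frameshifts are
  localized by global alignment to the closest full-ORF relative.
- **Structural domain grammar** — type-specific segmentation of the
  protein: α (signal, repetitive, QI, UI, QII, UII), γ (signal, I–V with
  the polyglutamine region as IV), ω (signal, N-terminal, repetitive,
  C-terminal). Polyglutamine tracts are maximal ≥6-residue windows with
  ≥80 % Q; repetitive domains are defined by coverage with the canonical
  repeat units (γ: PFPQ₁₋₂(PQQ)₁₋₂; ω: PFPQPQQ / PFPQQPQQ hepta- and
  octapeptides and their degenerate variants).
- **Celiac epitope and motif content** — exact (100 % identity) scanning
  against the curated DQ2.5/DQ8 epitope and immunoreactive-peptide
  library, near-miss (single-substitution) reporting, cysteine skeleton
  profiling (6 cysteines in α, 8 in γ, 0 in ω), repeat-unit counts, Q:P:F
  composition and ω-type (ARQ/E, KEL, SRL, TRQ) and α-group (I/II/III)
  classification.
- **Physicochemistry** — theoretical average MW and isoelectric point
  (Henderson–Hasselbalch bisection, Bjellqvist or EMBOSS pKa sets).
- **Expression** — RPKM (`C·10⁹ / (N·L)`) from uniquely-mapped count
  tables over grain development (5–25 days post-anthesis plus flag leaf),
  the >1000-RPKM expressed rule on grain stages only, peak-stage calls and
  the 70 % stability rule, and max/min fold summaries.
- **Proteomics** — in-silico chymotryptic digestion (cleavage after
  F/Y/W/L/M, never before proline), exact peptide-to-proteome matching,
  2-DE spot assignment (unique peptide ⇒ unique gene, otherwise the whole
  ambiguity group), percent-volume aggregation and spot/prediction
  consistency checks.
- **Synthetic families** — a codon-level generator that emits gliadin
  families with complete ground truth (domain boundaries, planted
  epitopes, C→T stop events, frameshifts, expression profiles, spot
  tables), so every pipeline stage is testable without downloads.

## Worked example

```r
library(gliadinR)

# a 28-gene family (23 alpha, 3 gamma, 2 omega; ~43 % pseudogenes)
fam <- generate_family(sim_config(seed = 1))
res <- run_annotate(fam$records,
                    gene_table = tibble::tibble(gene_name = fam$records$id))
res$summary$full_orf_by_type
#> alpha gamma omega
#>    14     1     1

head(res$catalogue[, c("gene_name", "status", "fragment_length",
                       "predicted_aa_length", "cysteine_count")], 2)
#>   gene_name      status fragment_length predicted_aa_length cysteine_count
#> 1 Gli-alpha-1  full_orf             708                 236              6
#> 2 Gli-alpha-2  full_orf             708                 236              6

ex <- generate_expression(fam)
er <- run_expression(ex$counts, ex$samples, ex$gene_lengths)
length(er$expressed)      # genes with any grain-stage mean RPKM > 1000
#> [1] 16
er$fold[["20"]]           # max/min fold at 20 DPA among expressed genes
#> $max_gene: "Gli-alpha-6"   $min_gene: "Gli-alpha-8"   $ratio: 16.45
```

Every full-ORF row obeys `fragment_length = 3 × predicted_aa_length`, the
cysteine counts reproduce the type-specific skeletons, and the expressed
set equals the full-ORF genes — the pseudogenes stay at background RPKM.
The same functions accept real data: `read_fasta()` for cloned CDS,
`read_gene_table()` for a catalogue TSV, `read_counts()`/`read_samples()`
for an RNA-Seq count matrix and `read_spot_table()` for a 2-DE spot table
(see `inst/extdata/` for the shipped catalogue and spot tables).

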