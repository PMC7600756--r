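---
title: "Methods: parental allele assignment in hybrid genomes"
author: "hybridtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parental allele assignment in hybrid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Allopolyploid hybrids such as the lager yeast *Saccharomyces pastorianus*
(*S. cerevisiae* × *S. eubayanus*) carry two sub-genomes plus lineage-specific
duplications and losses, often with unbalanced (aneuploid) chromosome copy
numbers. Functional annotation of such a genome requires deciding, for every
ORF, *which parent's gene* it descends from — a question general-purpose
annotation transfer does not answer, because it cannot restrict homology
search to the two parents, distinguish near-identical paralog copies, or
handle multiple copies of one locus.

`hybridtrace` answers it with reciprocal-best-hit orthology restricted to the
known parental genomes, paralog detection by self-alignment, transitive
homolog grouping, and an explicit multi-copy annotation step. All inputs are
nucleotide ORF FASTA files; all outputs are deterministic TSV tables.

## The procedure and its assumptions

**Alignment (3P+1 jobs).** For a hybrid and P parents (2–4), the pipeline
aligns hybrid↔parent in both directions (2P jobs) and every genome against
itself (P+1 jobs). Hits are local nucleotide alignments; only the single
best-scoring HSP per (query, subject) pair is kept, and only hits with
e-value ≤ 0.05 (`evalue_keep`) are saved. The underlying assumption, shared
with every BBH method, is that orthologs are each other's closest relatives
in sequence space — true when divergence between parents exceeds divergence
accumulated after hybridization.

**Best hits and orthologs.** A query's best hit is its minimum-e-value hit;
ties break by higher percent identity, longer alignment, then smallest
subject id (the source method does not state a tie rule; this chain is fixed
so outputs are reproducible). A best hit is *considered* only if it shares
strictly more than `identity_min` = 80% identity with the query — the filter
is applied to best hits of both directions **before** the reciprocity test,
so a high-identity second-best hit can never be promoted into a "best hit".
Orthologs are reciprocal best hits. Ids whose best hit failed only the
identity rule are carried forward separately (they form their own outcome
category); ids whose best hit passed the rule but was not reciprocated yield
no predicted allele at all.

**Allele assignment.** Per hybrid ORF, the parent whose ortholog has the
strictly highest identity wins (`ASSIGNED`); ties across parents are
`AMBIGUOUS_EQUAL_IDENTITY`. Ties are read at the 2-decimal precision
alignment tools report (`digits = 2`); `digits = Inf` compares exact values.
The four categories are mutually exclusive and exhaustive, so per-parent
assigned + ambiguous + subthreshold + no-prediction = total ORFs — the
partition identity every summary column must satisfy.

**Paralogs, groups, and multi-copy annotation.** Within a genome, identity
self-hits are removed, best hits recomputed, and reciprocal pairs kept as
paralogs. Pairs sharing a member merge transitively into homolog groups
(connected components; `igraph` under the hood, verified in tests against a
repeated-pass closure oracle). Because a 1:1 reciprocity test can only ever
match one of k near-identical copies of a gene, the pipeline ends with a
propagation step: an ORF with no prediction inherits the parental gene of
its highest-identity *assigned* partner in the hybrid self-alignment
(`origin = "homolog-group"`, iterated along chains of copies). The full
self-alignment hit table is used rather than only the BBH paralog pairs:
with three copies of one gene, the two unassigned copies are often each
other's mutual best hit, so the pair graph alone never reaches the assigned
copy. This step is what makes predicted copy numbers meaningful under
aneuploidy; it can be disabled (`propagate = FALSE`).

**Copy numbers and reports.** Copy number of a parental gene = number of
hybrid ORFs assigned to it; copy numbers sum to the ASSIGNED count. The
summary reports "number of different paralogs" in three candidate readings —
ORFs in ≥1 group (primary), number of groups, number of pairs — because the
quantity's published definition is ambiguous. With exactly two parents, the
shared-function report counts cross-parent ortholog pairs in which both
parental alleles were retained in the hybrid, and per-parent-only assigned
genes (the two-set Venn of inherited functions). Cross-parent orthology needs
2 alignment jobs beyond the core 3P+1 set and is opt-in
(`cross_parents = TRUE`).

## The built-in aligner

The pipeline logic depends on hit *ordering* and thresholds, not on exact
e-values, so the package includes a self-contained aligner:

* seeding: exact shared k-mers (k = 11) between query and subject (both
  strands by default); a pair becomes a candidate at ≥ `min_seeds` = 4 seed
  hits on a single diagonal (multi-hit seeding). For homologs the identity
  filter can use (> 80% identity, ≥ 150 nt), dozens of intact co-diagonal
  11-mers are expected (≈ L·0.8¹¹ ≈ 0.086 L), so this threshold costs no
  sensitivity; it exists to suppress random 11-mer collisions, which scatter
  across diagonals and would otherwise schedule full-width alignments
  between unrelated ~1 kb genes.
* extension: banded Smith–Waterman with affine gaps (match +2, mismatch −3,
  gap open 5, gap extend 2; a length-L gap costs 5 + 2L), compiled C++ with
  full traceback. The band covers the 10–90% quantile range of seed diagonals
  ± 16, capped at 256 diagonals — the trimmed range keeps repeated k-mers
  from inflating the band, while tolerating moderate indels.
* statistics: percent identity = identical columns / alignment columns × 100
  (N never counts as an identity, and any pair involving an ambiguity code
  scores as a mismatch); gap percentage = gap columns / alignment columns;
  e-value via Karlin–Altschul `E = K·m·n·exp(−λS)` with ungapped nucleotide
  constants λ = 0.625, K = 0.41. These e-values are approximate by design;
  the tests therefore compare the builtin and external blastn backends on
  best-subject *ranking*, not on e-values.

Correctness of the DP is established against an independent full
dynamic-programming oracle (`Biostrings::pairwiseAlignment`) on random
substitution + indel instances: scores and alignment lengths must agree
exactly when the band spans the matrix.

## The synthetic-data generator

`sim_config()` encodes the evolutionary scenario the pipeline targets:
ancestor ORFs (i.i.d. bases at GC 0.40, lengths ~ Normal(1000, 300) truncated
at ≥ 150 nt so seeding is always viable); each parent diverged by independent
per-site substitution (default 0.10), substitutions uniform over the three
alternative bases (Jukes–Cantor-like, no indels — this keeps truth identity
percentages analytically predictable; indel handling is exercised separately
through aligner fixtures); sparse small-scale duplications per branch
(default 0.02 per gene, with an extra substitution pass so duplicates are
distinguishable — the order of a few percent matches the sparseness of
curated yeast SSD paralog sets); and a hybrid sampling each parent gene at
its ploidy (default A:1, B:2, an approximately triploid Group-I-like
constitution), with per-copy loss (0.10), slight post-hybridization
divergence (0.005 — identifiability requires `div_posthyb < div_parent`,
warned otherwise), and post-hybridization duplications (0.02). Every hybrid
ORF's source parent, source gene and origin class are recorded.

What the generator does **not** emulate: chromosome structure and synteny,
translocations, recombination between sub-genomes, indel evolution, the
ohnolog divergence spectrum of the ancient whole-genome duplication, and
sequencing/assembly artifacts. Passing recovery tests therefore demonstrates
the correctness of the pipeline's logic under its stated assumptions — not
performance on real assemblies, where diverged paralogs and assembly
collapse add failure modes.

`score_recovery()` compares assignments to the truth: precision = correct
parent among ASSIGNED; recall = correct parent among *decidable* loci (an
ORF is undecidable when its source gene's sequence is identically present in
another parent — origin then unknowable in principle, the tRNA-like case);
copy-number error = predicted − true copies per parental gene. At the default
conditions (500 ancestor genes, seed 42) the full pipeline with the built-in
backend reaches precision, recall ≥ 0.99 over > 1300 decidable loci with
exact copy number for ≥ 95% of parental genes; the test suite and
`scripts/acceptance.R` recompute these, and the unit tests run the same
checks at smaller problem sizes (25–60 ancestor genes) chosen to keep the
suite quick.

## The genome-content test

For strains with observed per-parent allele counts and a ploidy model
(expected fractions per parent, e.g. 2:1 for a triploid with two sets from
one parent — `fractions_triploid()` — or 1:1 — `fractions_balanced()`), the
omnibus chi-square statistic is `Σ (O−E)²/E` over all strain × parent cells
with `E = strain total × fraction`, and **df = cells − 1**: all cells are
pooled into a single goodness-of-fit test rather than a contingency-table
test with (rows−1)(cols−1) df. This convention is the only one consistent
with the published critical value 18.48 at α = 0.01 for 4 strains × 2
parents (8 cells, df 7), and it is what `chi_square_gof()` implements.
`upper_tail_p()` stays accurate for extreme statistics (no underflow before
~1e-300): at the published statistic 865.44 with df 7 it returns 1.39e-182,
matching the published 1.3 × 10⁻¹⁸² to its printed (truncated) precision.
Because the expected-count construction behind the published statistic is
not stated, 865.44 itself is not regenerable from the published category
counts — fractions are therefore always user-specifiable per strain, and the
presets are offered as defaults only.

## Numerical and design choices

* Deterministic ordering everywhere: jobs in plan order, hits and pairs
  lexicographic, groups by smallest member; reruns of `run_pipeline()` on the
  same inputs give byte-identical files (md5s in `manifest.json`).
* Per-stage RNG streams derived from one seed; simulation helpers restore
  the caller's RNG state.
* FASTA ids are the first whitespace-delimited header token (BLAST's
  query-id convention), so hit tables join back to inputs without surprises.
* GFF3 rewriting sets `Name=` and preserves `ID=` by default, keeping
  `Parent` references valid; a strict `replace` mode substitutes ids and
  cascades to `Parent`, suffixing duplicates (`_copy2`, ...) to preserve GFF3
  id uniqueness. Columns 1–8 are emitted byte-identical; coordinates are
  never touched.
* Degenerate inputs: empty FASTA, duplicate ids, non-IUPAC residues,
  malformed GFF3 and tabular lines are hard errors naming the offending
  record/line; an all-lost simulated hybrid is a warning, not an error.
* Known limitations: no synteny awareness, no ohnolog-vs-SSD classification,
  no protein-level search, builtin e-values approximate, and paralogs that
  diverged beyond blastn-detectable identity are invisible to every stage —
  consistent with the method's published validation behaviour.
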