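---
title: "Comparative plastome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevo)
```

This vignette is the package's own account of the methods it implements: the
models and their assumptions, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical and
design choices made where the conventions in the literature are genuinely
open.

## The quadripartite model and inverted-repeat detection

A land-plant plastome is modeled as a circular string over {A,C,G,T,N}
partitioned into LSC, IRb, SSC and IRa, with IRb the exact reverse complement
of IRa and `|LSC| >= |SSC|`. Boundary detection searches for the
maximal-length pair of *exact* reverse-complement repeats, on the doubled
sequence so that repeats spanning the origin are found, and requires the two
occurrences to be disjoint on the circle. The two single-copy gaps are
labeled by length and the genome is reported in the orientation
LSC → IRb → SSC → IRa.

Exact matching is a deliberate choice: junction-calling from annotations
(as done by assembly/annotation servers) is not reproducible from a sequence
alone, whereas the maximal exact repeat is deterministic, testable, and
agrees with annotation-derived junctions whenever the two IR copies are
truly identical — the normal case for assembled plastomes, where the
assembler itself enforces identity. The minimum IR length defaults to
1,000 bp; shorter dispersed repeats are common enough that a smaller
threshold would risk spurious calls in IR-lacking genomes. Ambiguity
(several distinct maximal pairs of equal length) is reported as an error
listing the candidates rather than resolved silently.

All internal coordinates are 0-based half-open; GenBank I/O converts to and
from the 1-based inclusive file convention at the boundary. This keeps
interval arithmetic (region partition, exon splicing, SSR coordinates) free
of off-by-one special cases.

## CDS curation

Coding sequences are spliced across exons, reverse-complemented for
minus-strand genes, and retained only when their length is a multiple of
three and their translation under the plastid/bacterial genetic code
(translation table 11, whose 64-codon amino-acid map coincides with the
standard code) contains no internal stop. Failures are reported with a
reason, never silently repaired. Genes annotated twice — the inverted-repeat
duplicates — are collapsed to the copy with the lower start coordinate, so
that downstream orthologous comparisons treat each gene as single-copy.

## The codon-usage battery

**RSCU.** For codon *j* in an amino-acid family of `n_i` synonymous codons
with family total `X_i`, `RSCU = x_j n_i / X_i`. Met, Trp and the stops are
uninformative, leaving the standard 59-codon set; unobserved families are
left undefined at the per-gene level and completed with zeros only when
building the CA input matrix (a logged, explicit completion).

**ENC.** Wright's estimator with per-family homozygosity
`F = (n Σp² − 1)/(n − 1)` (the unbiased form; a switch allows raw `Σp²`),
family-size class means, `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at
61. Families with `n < 2` or `F <= 0` are omitted; a missing threefold class
(isoleucine unobserved) is imputed as `(F2 + F4)/2`, Wright's published
fallback; any other missing class leaves ENC undefined rather than
extrapolated. Two numerical consequences are worth knowing: the estimator is
exactly 20 when every family uses a single codon, and on perfectly uniform
usage it slightly exceeds 61 before capping (the unbiased correction
overshoots at finite counts) — hence the cap. Scale invariance under count
multiplication holds only in the large-count limit, again because of the
finite-sample correction.

**Expected ENC.** `ENC*(s) = 2 + s + 29/(s² + (1 − s)²)` with `s = GC3s`,
the no-selection reference curve against which observed ENC values are
read.

**Positional GC and PR2.** GC1/GC2/GC3 are computed over non-stop codons;
GC3s and the PR2 third-position counts additionally exclude Met and Trp,
consistent with the 59-codon convention. Whether PR2 should be restricted to
fourfold-degenerate families is not settled in the literature; both are
implemented (`fourfold_only` switch) and the default uses all informative
codons, the more common practice in plastome studies.

**Neutrality regression.** Unweighted ordinary least squares of per-gene
GC12 on GC3 (no gene-length weighting — the per-gene observations are the
sampling unit in this design). Zero GC3 variance flags the slope undefined;
constant GC12 yields slope 0 with R² defined as 0. Per-species statistics
are unweighted means over retained genes.

## Correspondence analysis

Classical CA: proportions `P`, row/column masses `r`, `c`, standardized
residuals `S = Dr^(−1/2)(P − rc')Dc^(−1/2)`, SVD, principal coordinates as
mass-scaled singular vectors times singular values. Total inertia equals
`Σσ²` and, identically, the chi-square statistic of the table over its grand
total — an identity the test suite checks to 1e-10. CA is run on per-gene
RSCU rows (a `counts` switch allows count-based CA, the statistically more
conventional choice for contingency tables; RSCU rows are the default
because that is the matrix this battery is defined on). Axes are deterministically
sign-fixed (largest-magnitude column loading positive) so coordinates are
reproducible across platforms; per-species CA over that species' genes is
the default granularity.

## SSR mining

Maximal perfect tandem repeats at unit lengths 1–10, with minimum copy
numbers 10 (mono), 6 (di), 5 (tri/tetra) and 3 (penta through deca). Runs
are reported once: at their primitive unit (an AT-run is never also a
mononucleotide run or a 4-mer "ATAT" run), at their leftmost phase, and with
complete copies only. Only interruption-free repeats are considered;
imperfect or compound SSRs are out of scope. A/C/G/T homopolymers are
retained as mononucleotide SSRs — the "homopolymer exclusion" sometimes
applied in repeat screens is interpreted here as exclusion of ambiguous-base
(N) artifacts, since mononucleotide SSR classes are reported throughout this
battery. The canonical motif is the lexicographically minimal rotation
*without* reverse-complement collapsing, so A- and T-homopolymers remain
distinct motifs, matching how plastome SSR tables are conventionally
reported. Loci duplicated by the IR are counted as printed coordinates
dictate (a `--dedupe-ir` style collapse is deliberately not the default).
Context classification uses the locus start position with priority
CDS > intron > intergenic spacer when features overlap.

Species clustering uses Jaccard distance on motif presence/absence with
average linkage; identical profiles merge at height zero, and ties resolve
deterministically through species-name ordering.

## Ka/Ks (NG86)

Orthologs are matched by gene name, all unordered species pairs per gene
(the all-vs-all design; pairs against a single reference would discard most
of the information in a 40-genome set). Translations are globally aligned
(match +1, mismatch −1, gap open −5, gap extend −1, a gap of length L
costing open + L·ext; traceback prefers diagonal, then up, then left),
back-translated, and every column containing a gap is removed.

NG86 counting: per codon, the synonymous site fraction is the per-position
fraction of one-step changes preserving the amino acid; changes *to* stop
codons count as nonsynonymous so that S + N = 3L holds exactly. Observed
differences are averaged over all mutational pathways (2 orderings for two
differences, 6 for three), excluding pathways that pass through a stop
codon; codon pairs with no stop-free pathway are skipped and counted. The
64×64 site and pathway tables are precomputed once, making per-pair
estimation a table lookup. Proportions are Jukes–Cantor corrected,
`d = −(3/4)ln(1 − 4p/3)`; the ratio is undefined when `dS = 0` or a
proportion reaches 3/4, and such pairs are excluded from summaries — the
same spirit as the ratio > 10 outlier rule applied before the category
statistics.

A known small-sample artifact: at appreciable divergence, pathway averaging
can attribute fractional nonsynonymous differences to codon pairs whose
history was purely synonymous (e.g. Leu TTG vs CTC), so Ka is exactly zero
under a synonymous-only history only at low divergence.

Category statistics follow the battery's conventions: one-sample t-tests of
each category's ratios against 1 with Bonferroni correction over categories;
all between-category Wilcoxon rank-sum tests with Bonferroni correction over
the number of comparisons; Cohen's d with pooled SD, signed first-minus-second
in report order; per-category Pearson correlation between Ka and Ks.

## Synteny and phylogeny

Synteny is computed from shared annotated gene order (signed by strand),
not from nucleotide alignment: collinear blocks are maximal runs where the
signed index advances by one, breakpoints are block count minus one, and the
collinear fraction is the share of shared genes in runs of length at least
two. Gene orders are compared as annotated (linear from the origin); a
rotation of one genome relative to the other will appear as one extra
breakpoint, which is acceptable at the desk scale this report targets.

The tree stage is a self-contained distance pipeline: genes concatenated in
lexicographic order with gap padding for missing species and a
column-occupancy filter (default: drop columns under 50% occupancy),
Jukes–Cantor distances with pairwise deletion, and Saitou–Nei neighbor
joining with deterministic lowest-index tie-breaking; negative branch
lengths are clamped to zero with the deficit recorded. Maximum-likelihood
inference with external programs is deliberately out of scope, so ML branch
lengths from published analyses are treated as non-reproducible anchors;
what the NJ stand-in supports is topology-level congruence, which the tests
exercise through exact recovery of additive matrices. Branch-rate summaries
use *terminal* branch lengths per genus (mean and SD; SD absent for
singletons) — root-to-tip averaging is the other defensible reading, and
terminal-branch semantics were chosen because they isolate recent,
lineage-specific rate variation.

## The synthetic-data generator

The generator emulates the statistical structure this battery consumes:
a circular quadripartite genome (defaults 85,994 / 608 / 37,024 bp —
an IR-expanded, extremely SSC-contracted configuration totalling
160,650 bp), AT-rich intergenic filler (65% AT), protein-coding genes built
from sense codons with third positions biased to a target GC3 of 0.27 and a
milder AT bias at positions 1–2, planted perfect SSRs with period-breaking
flanking bases (so their coordinates are exact and maximal by construction),
and IR genes mirrored into both copies. Orthologs evolve by codon-level
rejection sampling: proposals at the branch-length rate, stop-creating
proposals rejected, synonymous proposals always accepted, nonsynonymous
accepted with probability ω. This is an approximation to a full codon
substitution model (no rate matrix, no transition/transversion structure,
no indels); it is sufficient because the package only asserts rank-order and
approximate recovery of ω, not likelihood-level equivalence. All randomness
derives from the config seed; outputs are byte-identical across runs.

What the generator does *not* emulate — annotation errors, IR boundary
shifts over time, compound/imperfect SSRs, recombination, heteroplasmy,
real codon-usage covariance between genes — bounds what passing tests show:
they validate the estimators and the plumbing on data satisfying the model's
assumptions, not robustness to the full messiness of archived genomes.

## Problem sizes and numerical conventions

The test suite and examples run at desk scale: simulated genomes of 9–160 kb,
gene sets of tens of genes, 100-replicate property checks (random 5 kb
sequences for the SSR oracle, random 5-leaf additive matrices for NJ), and
ω-recovery at 200 ortholog pairs of 150 codons, which recovers ω = 0.2
within ±0.05. Degenerate inputs follow a consistent convention throughout:
undefined quantities are NA with a reason flag (never silent zeros, never
exceptions for expected edge cases), and genuinely malformed inputs raise
errors naming the offending gene, pair or file.
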