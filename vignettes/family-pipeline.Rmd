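---
title: "Methods: genome-wide survey of a domain-defined gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide survey of a domain-defined gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

famscan implements the standard workflow for a genome-wide survey of a
transcription-factor family defined by a conserved protein domain — the
kind of analysis routinely published for plant bHLH, WRKY or MYB
families. This vignette is the package's account of the methods: the
model behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Identification

A family survey starts from a proteome and its genome annotation. The
domain is represented as a position-specific log-odds profile built
from a user-supplied seed alignment:

$$\mathrm{score}_j(a) = \log_2 \frac{(c_{j,a} + \tau\, b_a)/(n_j + \tau)}{b_a}$$

where $c_{j,a}$ counts residue $a$ in alignment column $j$, $n_j$ is
the number of residues observed in that column, $b$ is the background
frequency (uniform over the 20 residues by default) and $\tau$ is a
pseudocount weight (default 1). Columns with more than 50% gaps are
dropped. This is a deliberate simplification of a full profile HMM: it
has no position-specific transition probabilities, which keeps the
model reproducible from any seed alignment without an external model
file. The trade-off is weaker sensitivity to remote homologs; for
family surveys the downstream completeness filter, not raw
sensitivity, is the decisive criterion.

Scanning is *glocal* dynamic programming: the profile is global (every
column must be matched or deleted, with affine internal gap costs,
default open 11 / extend 1 bits, a gap of length $k$ costing
$\mathrm{open} + (k-1)\,\mathrm{ext}$) while the target is local (free
overhangs, affine internal insertions). A placement is reported when
its score reaches 0 bits — a neutral log-odds cutoff; the operative
filter is **domain completeness**: a gene is accepted only when the
best hit covers at least 90% of the profile columns
(`completeness_min = 0.9`). This single internal rule replaces the
common practice of cross-checking candidates against several web
databases, which is not reproducible offline.

Loci carry several transcripts; only one protein represents each
locus. The representative transcript is the one with the **longest
total CDS** (ties broken by smallest transcript id) — the standard
proxy used by genome consortia for their "representative models" when
no explicit flag is available.

Accepted members are named by chromosomal order: chromosomes in
declared order (an unanchored pseudo-chromosome, `chr00`, is declared
first and therefore named first), then start coordinate, then gene id.
All genomic coordinates are 1-based inclusive (the GFF3 convention);
the only place where ±1 interval arithmetic occurs is `iv_width()`.

## Characterization

Protein length, molecular weight and isoelectric point mirror the
usual ExPASy-style report. MW uses average (not monoisotopic) residue
masses plus one water per chain; `X` contributes the mean residue mass
and no charge. pI solves net charge = 0 by bisection on the
Henderson–Hasselbalch charge curve using a Bjellqvist-style pKa set
(N-terminus 9.094, C-terminus 2.869, side chains C 7.555, D 3.872,
E 4.412, H 5.637, K 9.052, R 11.84, Y 10.85), to a residual charge
below 1e-4. The pKa table is exposed in `default_pka()` because
published pI values vary with the table chosen; the default reproduces
the ExPASy-style convention.

Intron phases follow the standard convention: the phase of intron $i$
is the cumulative CDS length upstream of it modulo 3 (phase 0 =
splicing after a complete codon). Minus-strand transcripts are handled
once, at GFF3 parse time, by storing exons and CDS segments in
transcription order; everything downstream is strand-agnostic.

Motif architectures use exact bracket-consensus matching (e.g.
`[PK][PK]KDY[IV]HVRA`; `X` = any residue): a motif occurs at the
leftmost window where every residue is in the allowed set, and at most
one occurrence per motif is recorded per protein. No mismatch scoring
is attempted: the shipped 20-motif set (`stbhlh_motifs()`) is given as
hard consensus sets, not as scoring matrices, and de novo motif
discovery is out of scope.

## Duplication calling

Every unordered pair of members is globally aligned
(Needleman–Wunsch/Gotoh, BLOSUM62, gap open 10 / extend 1). A pair is
a duplication when, strictly, coverage > 70% **and** similarity > 70%,
where coverage is the fraction of the longer sequence aligned
residue-to-residue and similarity is the identity fraction over
aligned columns (gap-versus-residue columns count as mismatches).
"Similarity" is read as identity — the strictest reproducible
interpretation; a conservative-substitution grouping would need an
arbitrary similarity grouping table and is intentionally not the
default.

A called pair is **tandem** when both genes lie on the same chromosome
within 100 kb (start-to-start) and are separated by at most five genes
of the *whole-genome* annotation (not family members only); tandem
pairs merge into clusters by single linkage. Remaining called pairs
are **segmental** when on different chromosomes or at least 100 kb
apart. This closed rule replaces lookups in an external synteny
database, which are version-dependent; the cost is that "segmental"
here means "duplicated but not tandem" rather than
"synteny-confirmed". Same-chromosome pairs inside the window but with
too many intervening genes stay `unclassified`. The 100 kb window is
measured start-to-start; measuring end-to-start changes calls only for
genes longer than the gap between them, which does not occur at this
scale.

## Phylogeny and subfamilies

Distances are Poisson-corrected proportions of differing sites with
**pairwise deletion**: for each pair, only columns ungapped in both
sequences are compared; $p$ is the mismatch fraction and
$d = -\ln(1 - p)$. A pair differing at every comparable site (or with
no comparable sites) has no defined distance and is an error — in
bootstrap replicates such cases are skipped and removed from the
denominator.

Trees are Saitou–Nei Neighbor-joining, joining the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, with the
standard branch-length formulas. Ties in $Q$ break to the
lexicographically smallest pair of representative leaf labels, making
results platform-independent. Tiny negative branch lengths (a known NJ
artifact on non-additive data) are clamped to zero with a warning. On
additive matrices NJ is exact; the test suite verifies topology and
path-length recovery against brute-force topology enumeration with
least-squares branch fitting.

Bootstrap supports resample alignment columns with replacement,
rebuild distance matrix and tree, and report for each internal edge
the percentage of successful replicates containing the same leaf
bipartition, attached as internal node labels (the display convention
of common tree software). Supports are reported on the full-data tree,
not a consensus tree.

Subfamily assignment takes a tree containing both query leaves and
labelled references. The rule: among all edges with support at least
`support_min` (default 50) whose query-containing side holds at least
one reference, the smallest such side decides — one label assigns it,
several labels mean the query sits in a mixed clade and stays
`unassigned`. This "smallest supported clade containing the query and
a reference" reading makes the two boundary cases exact: a query
sister to a single supported reference inherits its label, and a query
inside a clade that is label-mixed at every supported edge is
unassigned. Pendant edges count as fully supported (a single leaf is
trivially a clade); a tree without node labels is treated as fully
supported throughout.

Multiple sequence alignment itself is not a contribution of this
package: the pipeline accepts any precomputed alignment. For the
self-contained synthetic path a small progressive aligner
(`align_proteins()`) is included: pairwise Gotoh identities give a
distance matrix, an average-linkage (UPGMA) guide tree orders the
merges — chosen over an NJ guide tree because the `hclust` merge list
is already a rooted traversal order, where an unrooted NJ tree would
need an arbitrary rooting step — and profiles merge by
profile–profile Needleman–Wunsch with count-weighted mean BLOSUM62
column scores. It is adequate for the generator's sequence divergence;
real datasets should use a dedicated MSA tool.

## Expression and qPCR

FPKM matrices are equalized by the **grand mean of the whole matrix**
(one scalar — the literal reading of mean-equalization; a per-row
variant is available via `by_row = TRUE` for comparison), then
log2-transformed after adding a pseudocount of 0.01 so FPKM = 0 stays
finite while ordering is preserved. Genes with FPKM below 2 in every
condition are "barely expressed" and excluded (strict `<`: a gene
exactly at 2 in some condition is kept). Heatmap row ordering is
average-linkage (UPGMA) clustering on Euclidean distances between
logged rows; average linkage is monotone, so merge heights never
decrease. The distance metric is configurable
(`euclidean`/`correlation`); rows are not re-scaled after log2 by
default.

qPCR quantification follows the 2^−ΔCt / 2^−ΔΔCt convention with
three biological × two technical replicates as the default layout.
Technical replicates average to one Cq per biological replicate first
(standard practice); ΔCt = Cq(target) − Cq(reference) per biological
replicate; in ΔΔCt mode the mean control ΔCt is subtracted. The
reported fold is `2^(-mean(ΔΔCt))` — the fold of the mean rather than
the mean of per-replicate folds — so the calibrator condition's fold
is exactly 1 by construction; the per-replicate fold standard
deviation is reported as the dispersion. Amplification-efficiency
correction is out of scope.

## The synthetic-data generator

`generate_family_genome()` plants ground truth for every stage: a
hidden domain consensus; a 20-sequence seed alignment at 6%
divergence (the identification profile is built from this alignment,
never from the hidden consensus, so profile building is exercised
honestly); members carrying the full domain; decoys carrying at most
half of it or none; loci with 1–3 transcripts whose representative
(longest-CDS) transcript encodes the full protein; tandem clusters as
consecutive high-similarity genes within 100 kb (with occasional
intervening decoys); segmental pairs on different chromosomes;
labelled subfamilies descended from independent ancestors; and a
planted barely-expressed subset whose FPKM is drawn uniformly in
[0, 2) — making the expression filter a sharp oracle.

Divergence is structured the way real families are: the domain is
conserved (ancestor 2% from consensus, members +3%), flanking regions
are divergent (30% per lineage within a subfamily), and planted
duplicate pairs/clusters are recent (5% whole-protein divergence).
Consequently non-duplicate members of the same subfamily sit near or
below the 70% identity line while planted duplicates sit well above
it, and subfamily clades are unambiguous. Default scale: 24 members,
12 decoys, clusters of 3+2, 2 segmental pairs, 4 subfamilies with 3
references each, on 5 anchored chromosomes plus `chr00` holding 2
unanchored members; 12 tissues at baseline FPKM 20 with log-noise
0.25 and a quarter of members unexpressed. All randomness flows from
one integer seed through R's generator; identical (config, seed)
give byte-identical files.

What the generator does **not** emulate: codon usage and nucleotide-
level evolution, paralog birth–death dynamics, alignment-fragmenting
indels, read-level RNA-seq noise, or FPKM compositional biases.
Passing the planted-truth tests therefore shows the pipeline's logic
is correct under its stated assumptions, not that the thresholds are
optimal for any particular real genome.

## Problem sizes and determinism

The test suite runs the full pipeline at the default generator scale
(24 members + 12 decoys), checks the alignment kernel against
exhaustive enumeration on 200 short pairs, NJ against 100 random
additive trees (with brute-force topology enumeration on the 4–6 leaf
cases), the pI solver against a 1e-5-resolution pH grid, and bootstrap
calibration at 100 replicates on a 4-clade, 20-sequence, 300-column
alignment — sizes chosen so the whole suite completes in about a
minute while every oracle remains genuinely exhaustive. Bootstrap
replicate counts are a parameter (`bootstrap_replicates`); published
analyses conventionally use 1000.

Stage outputs are plain TSV/Newick files written per run; there is no
result caching — the pipeline at this scale runs in seconds and a
cache would complicate the determinism guarantee (same inputs, config
and seed give identical outputs, including bootstrap supports).

## Known limitations

- The profile scan is not a full profile HMM; extremely divergent
  domain copies may score below members that a calibrated HMM with
  E-values would rank correctly.
- "Segmental" means "duplicated and not tandem", without synteny
  confirmation.
- The subfamily rule assigns from the single smallest supported
  clade; a query equidistant between two clean reference clades is
  decided by that clade alone rather than by any voting scheme.
- The built-in progressive aligner is for the synthetic path;
  alignment quality on real, indel-rich families is better served by
  dedicated MSA software, and the pipeline accepts such alignments
  directly.
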