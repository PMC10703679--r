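---
title: "Methods: dual-primer combinatorial-indexing RNA-seq processing in sciduet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-primer combinatorial-indexing RNA-seq processing in sciduet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciduet)
```

# The data-generating process

A three-level combinatorial-indexing RNA-seq library tags each nucleus with
an RT index (which also encodes the sample and the reverse-transcription
primer class), a ligation index and a PCR index. Two RT primer classes are
used side by side: an indexed short oligo-dT primer, which captures
polyadenylated 3′ ends, and an indexed random hexamer, which captures
internal sequence. Until the QC merge, the two classes of one physical cell
are treated as independent pseudo-cells — the string form of a cell barcode
is `sample.rtwell.ligwell.primer`.

This document explains the statistical and algorithmic choices in each
stage, the tunable parameters, and exactly what the synthetic fixtures do
and do not emulate.

# Demultiplexing

Read 1 carries `ligation index (10 bp) + UMI (8 bp) + RT index (10 bp)`;
read 2 is cDNA. The layout is configuration (`read_layout()`), not code,
because oligo architectures differ between kit versions. Each index is
corrected against its whitelist tolerating at most one mismatch
(`max_barcode_mismatch = 1`, i.e. edit distance < 2) under **Hamming**
distance — indices sit at fixed offsets, so insertions/deletions present as
multiple substitutions and are correctly rejected. An observation equally
close to two whitelist entries is rejected as ambiguous rather than
assigned: mis-assignment contaminates another cell, whereas rejection only
loses a read. Whitelists synthesized with minimum pairwise distance 3 make
one-mismatch correction provably unambiguous.

Poly(A)/quality trimming removes, from the 3′ end, bases below quality 20
and then the longest terminal run that begins with an A, has length ≥ 10,
and contains at most one non-A base per ten (sequencing errors inside a
tail). Requiring the run to begin with A prevents a single upstream
mismatch from dragging genuine cDNA bases into the tail.

# Gene and exon assignment

Aligned fragments (SAM/BAM; mates sharing a read name are unioned into one
fragment) are deduplicated per cell on the key (cell, UMI, chromosome,
fragment start, strand) — the start rather than the end anchors the key
because the 3′ end varies with trimming. UMIs are compared exactly; an
8 bp UMI at fixture depths makes one-mismatch UMI collapse a negligible
correction, and the alternative is noted as future work.

Assignment priority per deduplicated fragment:

1. **Sense overlap.** One overlapping same-strand gene → assigned.
   Several: an oligo-dT fragment goes to the gene with the closest
   annotated 3′ end (dT priming means fragments concentrate at transcript
   ends); a random-hexamer fragment is ambiguous and not counted. The
   3′ distance is |fragment midpoint − gene 3′ end|; exact ties break
   lexicographically by gene ID so the rule is deterministic.
2. **Upstream rescue.** With no sense overlap, a same-strand gene whose 3′
   terminus lies within 1,000 bp upstream of the fragment is accepted:
   dT reads frequently fall just past annotated 3′ ends. The window is
   strand-relative (a + strand fragment searches lower coordinates). When
   several genes qualify, the nearest 3′ end wins — the same metric as the
   tie-break, applied for the same reason.
3. **Antisense rescue.** A uniquely overlapping opposite-strand gene;
   several antisense candidates are ambiguous.
4. Everything else is discarded (fragments on chromosomes absent from the
   annotation are discarded under a separate counter).

Exon assignment within the assigned gene keeps the unique overlapping
exon, or the exon with maximal overlap (ties → none, intronic → none);
gene-level counts are unaffected. All coordinates are internally 0-based
half-open; GTF (1-based inclusive) and SAM (1-based) are converted on
ingest, so a single convention holds everywhere.

Per-cell accounting satisfies, exactly and by construction,
`assigned + ambiguous + discarded + duplicates = total fragments`, and
`unassigned_frac = (ambiguous + discarded) / total`.

# QC

Physical cells must be seen by **both** primer classes; kept cells' counts
are element-wise sums of their dT and randomN columns, and the unassigned
fraction is pooled over both columns (the filter applies to the physical
cell, after the merge). The three filters use strict inequalities —
unassigned > 30%, UMIs > 20,000, genes < 200 — so boundary values pass;
every violated criterion is recorded, and doublet scores computed by an
external scorer remove cells strictly above the threshold.

# Subclustering with exon information

Log-normalized (`log1p(1e5 · x / libsize)`) gene and exon matrices are
reduced separately to 30 and 10 principal components, concatenated
(`[gene PCs | exon PCs]`), and clustered by Louvain on a Jaccard-weighted
shared-nearest-neighbor graph. Exon usage shifts that leave gene totals
unchanged — alternative 3′ ends, retained exons — are invisible to the
gene block but separate cells in the exon block; the package's fixture
plants exactly this situation (two clusters with identical gene means and
different exon usage). A rank-deficient block contributes only its rank,
recorded in the embedding provenance.

The number of PCs for *main*-type clustering is not fixed by the protocol;
the subclustering values (30 + 10) are used as defaults with the Louvain
resolution (1.0) and neighborhood size (20) exposed in the configuration.
"Subclusters not readily distinguishable in the 2-D embedding" is a manual
step in practice; it is made deterministic here: iteratively merge the
closest cluster pair whose centroid distance is below `min_sep` (default 1)
times the pooled median within-cluster radius, until no pair qualifies.

# Differential expression and abundance

Both tests are negative-binomial GLM likelihood-ratio tests. For
expression: full model `counts ~ group + sex` vs reduced `~ sex`, with a
log library-size offset; the dispersion is moment-estimated per feature
from Pearson residuals of a Poisson fit (underdispersion clips to a
near-Poisson size parameter), and the LRT statistic is referred to
χ²(Δdf). For abundance: replicate = RT well, response = cells per
subcluster, offset = log total cells of the replicate — so the tested
quantity is the subcluster's population fraction; sex is a covariate by
default (`abundance_sex_covariate`, a documented switch, since the
protocol states the covariate explicitly only for expression). Fold change
uses condition-pooled fractions with a 1e-5 pseudocount added to both,
which keeps FC(a,b)·FC(b,a) = 1 and damps tiny clusters. Calls: up if
FC > 2 and q < 0.05; down if FC < 0.5 and q < 0.05; excluded if either sex
contributes fewer than 20 cells. Multiple testing is Benjamini–Hochberg
throughout.

Marker selection: q < 0.05, over twofold between the first- and
second-ranked cell types, TPM > 50 in the first-ranked type ("TPM" for UMI
counts means counts-per-million within the group; no length normalization
is meaningful for UMI data). The condition-level DE variant keeps
q < 0.05, FC > 1.5 and TPM > 50.

# Spatial NNLS

Cell-type signatures are aggregated UMI counts, library-size normalized,
×100,000, log1p — and spots are normalized identically. Each spot solves
min‖S·w − y‖₂ over w ≥ 0 by the Lawson–Hanson active-set method;
Karush–Kuhn–Tucker conditions (gradient ≥ 0 on the zero set, complementary
slackness) are verified at every solution and the worst violation is
reported. Weights are returned raw and as per-spot proportions, since both
views are used (dominant-type maps vs fraction maps). The protocol does not
state whether spots share the ×100,000 scale; the package normalizes both
sides identically, which the scale-invariance of NNLS proportions makes
harmless.

# Gene modules

Subcluster pseudobulk is library-size normalized; genes are kept when the
maximum across subclusters is ≥ 1 and the maximum/median ratio is ≥ 5. The
ratio is computed on the **linear** normalized scale — a ratio of log
values would penalize highly expressed genes, contradicting the filter's
variance-selection intent — and a zero median is replaced by the smallest
positive value in the matrix, so strongly expressed genes silent in most
subclusters are retained. The log1p matrix then feeds a cosine UMAP
(min_dist = 0.01, n_neighbors = 30) with PCA initialization: the default
spectral initialization scatters disconnected neighbor-graph components
arbitrarily, which fragments clean module structure; PCA initialization is
deterministic and connectivity-independent.

Density-peak (Rodriguez–Laio) clustering on the 2-D coordinates uses a
Gaussian kernel with the cutoff distance pinned to the 2nd percentile of
pairwise distances (the cited package's default, made explicit for
determinism). ρ is the kernel-weighted local density; δ is the distance to
the nearest higher-density point (the global peak takes the maximum
pairwise distance); centers satisfy ρ > 1 and δ > 1 and remaining points
join their nearest-higher-density neighbor's module in decreasing-density
order, with density ties broken by point index.

# Peak-side statistics and peak–gene linkage

Peak scores (−log10 q) are converted to score-per-million (score / total
score × 1e6, cutoff 1.3) to harmonize confidence across groups of
different depth. Summits are padded ±250 bp and merged; the merge never
shrinks an input interval, making it idempotent. Accessibility is binary:
a cell is accessible at a peak iff any fragment overlaps it.

Linkage: genes and peaks with maximum TPM > 10 across subcluster
pseudo-cells form candidate pairs when the peak center lies within
±500 kb of the TSS. Pearson correlations across pseudo-cells are compared
with a null built by permuting the subcluster identity of the ATAC matrix.
The retention threshold is the smallest observed PCC t with
(#permuted ≥ t / rounds) / (#observed ≥ t) ≤ 0.01, estimated on the
positive tail (only positive links are retained). The default pools **10
permutation rounds**: with a single round the threshold cannot resolve
tail probabilities below ~1/#candidates, which roughly doubles the
realized FDR at these problem sizes; pooling rounds is purely a precision
improvement of the same estimator. Per peak only the best-correlated gene
is kept, and distal peaks overlapping another gene's promoter (TSS ± 2 kb,
configurable) are removed. Peak centers anchor the window and TSS ± 2 kb
defines promoters — both common conventions, pinned because the procedure
must be deterministic.

TF analysis: the single-cell motif-deviation matrix is min–max rescaled to
(0, 10) in one global (monotone) transformation — a per-cell rescale would
destroy cross-cell structure when few motifs are scored — then both the
deviation and TF-expression matrices are aggregated per cell type,
z-scaled across types, and correlated per TF.

# Aging clock

Within each (animal, cell type), cells are randomly binned into groups of
about 15 and averaged on the normalized scale; bins never span animals, so
no pseudobulk mixes ages. Per cell type, ridge regression predicts ln(age)
from standardized pseudobulk expression. The solution is computed in
closed form via SVD (exact to machine precision; the normal-equations
identity is a test oracle) with the penalty chosen by 5-fold
cross-validation over a log grid from 1e-8 to 1e4 — the protocol states no
penalty, and a grid with CV avoids an arbitrary constant while letting
noiseless data drive the penalty to zero. The 80/20 split is stratified by
animal: pseudobulks of one animal are correlated, and splitting them
across train and test would leak. Random binning (rather than expression
k-means) is the default and a documented toggle. Age acceleration is
predicted minus chronological ln(age) for samples never used in training.

# What the fixtures emulate — and what they do not

The generators (`fixture_spec()` and the `make_*` / `simulate_*` family)
produce: a toy genome whose gene layout forces every assignment branch
(a same-strand overlapping pair for the 3′ tie-break, an opposite-strand
pair, gaps wider than the rescue window); paired FASTQ with planted 0/1/2
barcode errors (two-error barcodes are resampled until they sit at
distance ≥ 2 from every whitelist entry, so their planted rejection is
certain) and planted exact duplicates; a SAM placing each read at its true
locus; and count matrices with planted clusters (including the exon-usage
twins), composition shifts, gene modules, peak–gene links and ln(age)
signal, under negative-binomial count noise (downstream LRTs assume
overdispersed counts).

Default study conditions: 2 samples × 4 RT wells, 60 cells, ~40 reads per
cell per primer class, 40% random-hexamer reads, 5%/2% one-/two-error
reads, 10% duplicates; 3–4 expression clusters of equal size at NB
dispersion 0.2; abundance datasets of 20 subclusters × 4 wells per
condition; 4 modules × 50 genes with log-normal within-module spread 0.8
(near-duplicate member profiles are a degenerate input for UMAP and
unlike real modules, which show graded correlation); 50 planted links
among 5,000 decoy peaks over 30 pseudo-cells; ages 3/6/21 months × 4
animals. The exon-twin clustering condition uses three equal clusters (one
gene-distinct plus the twin pair) — the minimal construction in which
gene-only clustering is structurally unable to recover the truth.

What passing tests do **not** show about real data: fixtures have uniform
base quality and error-free alignment (alignment itself is out of scope —
the SAM is ground truth); barcode errors are uniform substitutions, not
sequencer-specific profiles; cluster signatures are block-structured rather
than gradient-like; spatial spots are exact mixtures of signatures rather
than segmented tissue; and the permutation null for linkage is exchangeable
by construction, which real batch structure can violate.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run on fixture scales chosen
to keep the full suite in minutes on one CPU: 2,600-read libraries,
300-cell clustering problems, 200 null simulations for abundance
calibration, 2,000 features for LRT uniformity, ten linkage fixtures of
5,050 peaks. The realized linkage FDR at 50 true links carries Poisson
noise of ±1 false call, so it is measured pooled over the ten fixtures
rather than per fixture.

# Known limitations

* UMIs are compared exactly; no within-1-mismatch UMI collapse.
* Multi-mapping reads are skipped (primary alignments only); no
  transcript-isoform quantification beyond exon counts.
* Compositional alternatives for abundance testing (CLR transforms,
  mixed-effects models) are noted as future work.
* Doublet scoring, peak calling and motif-deviation computation are
  consumed from external tools, not reimplemented.
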