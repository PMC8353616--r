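---
title: "pasflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pasflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pasflow analyses alternative polyadenylation (APA) from 3' tag-based
single-cell RNA-seq. Oligo(dT)-primed protocols (10x Chromium and kin)
pile their read 5' starts in the few hundred nucleotides upstream of each
cleavage-and-polyadenylation site (PAS), so PASs can be located, vetted
and quantified directly from the standard alignments. The pipeline runs
in four stages: fixed-width peak calling at transcript level, sequence
classification of candidate sites with a convolutional + BiLSTM network,
UMI counting per cell barcode over a PAS-based transcript annotation, and
proximal-usage statistics across cells. This vignette records the models,
the tunable parameters and the design decisions, in the order the
pipeline runs them.

## Peak calling

Reads are projected per transcript. Exon-overlapping read starts are
mapped through the splice structure into spliced coordinates, so a called
peak can span an exon junction and maps back to a multi-block genomic
footprint; intron-contained starts are scanned in genomic coordinates
within the transcript span. Spliced space cannot by construction produce
an intronic 3' end, so intronic candidates — the internal-priming-prone
class — require this second scan; the two scans together cover the whole
locus.

Calling itself is a greedy fixed-width scan of strand-specific read-start
coverage. Candidate windows of `size` (default 400 nt, the typical 3' tag
peak width) are ranked by the number of unclaimed read starts they
contain; the best window claims its reads and calling repeats until no
window holds `min_count` (default 10) starts. Two accepted windows must
have summits more than `min_dist` (default 10 nt) apart. Among tied
maximal windows the most 3' placement wins: read starts stop roughly 50 nt
short of the cleavage site, so anchoring the window's downstream edge at
the downstream-most covered position puts the reported 3' end at (or just
upstream of) the site, and for an internal-priming artifact at the A-run
that primed it — which is what lets the artifact filter see the run.

Each peak's read-start profile is then assessed for modality. The dip
statistic — the sup-norm distance from the empirical cdf of start
positions to the nearest unimodal cdf — is computed exactly by a
convex/concave hull band construction (`src/dip.cpp`). Large profiles
are quantile-downsampled to a small grid of sizes (at most 201
positions) so a handful of Monte Carlo null tables (200 uniform samples
each, cached per session) covers every peak; the statistic is never
computed on more points than the profile holds, because the dip shrinks
with sample size and an inflated-n comparison would over-call
multimodality. Profiles with
dip p <= 0.05 are split at the deepest smoothed-coverage minimum between
the two highest modes; children partition the parent's reads. An
Anderson-Darling normality p value (via nortest) is reported as metadata
only. The reference literature runs both tests but does not state the
action taken on their outcomes; splitting on dip rejection is this
package's choice, and disabling it (`split_multimodal_peaks = FALSE`)
leaves flagged peaks intact.

After calling: peaks of the same gene overlapping by at least 50% of the
shorter peak's width are grouped transitively and only the most expressed
member survives; peaks contributing <= 1% of their gene's summed counts
are dropped; and intronic peaks whose strand-oriented sequence in
[3' end − 30, 3' end + 20] contains >= 8 consecutive adenines are removed
as internal-priming artifacts. The scan window is a package choice (the
adenine-run rule itself is standard): 20 nt downstream covers the
oligo(dT) annealing stretch, and 30 nt upstream absorbs the placement
jitter of the fixed-width caller — the reported 3' end sits up to a few
tens of nt downstream of the priming locus depending on where the
upstream-most read of the pileup fell — while keeping the chance of an
accidental 8-run in background sequence negligible.

## The sequence classifier

Candidate 3' ends are vetted by sequence alone. A 200-nt strand-oriented
window centered on the site is one-hot coded (channel order A, T, G, C;
N is an all-zero column; windows over 10% N are rejected from training)
and passed through, in order: a convolution of 128 filters x width 12
over 4 channels with ReLU; a convolution of 64 filters x width 6 with
ReLU; max pooling with window = stride = 4 (the pooling window is not
separately specified upstream; tying it to the stride is the
conventional reading); a bidirectional LSTM with 128 units per direction
whose last states feed a 1024-unit ReLU dense layer with dropout 0.3;
and a 2-unit softmax. A site is positive when the positive-class
probability exceeds 0.5 (exactly 0.5 is negative). The implementation is
RcppArmadillo throughout — im2col convolutions, explicit backpropagation
through time, Adam (rate 1e-3), cross-entropy loss — and all randomness
(initialization, shuffling, dropout) derives from one seed, so a run is
reproducible bit-for-bit on the same BLAS. Widths scale down uniformly
(`pasnet_spec(scale = )`) for desk-scale models; the layer order never
changes.

Training sets follow the shifting scheme. Positives are windows around
annotated stringent sites — those reported by all three PAS databases or
by the curated gene annotation; known sites require two databases or the
annotation — shifted by round(Normal(0, 10)) nt, 10 distinct offsets per
site (resampled until distinct, capped at |90| so the cleavage site stays
inside the window), then deduplicated by exact sequence. At corpus scale
this is 251,071 stringent sites split 9:1 (225,964 / 25,107; the training
size rounds half up) and 2,259,640 shifted positives with matched
negatives. The fixed-position variant takes the single centered window
per site. Negatives are sampled uniformly from intergenic space,
rejected if they contain any annotated site, and deduplicated. Early
stopping monitors a 5% holdout of the training examples (the validation
split proper is reserved for evaluation): training stops after `patience`
epochs without strict improvement and the best-epoch parameters are kept.

## The synthetic benchmark and what it shows

No real PAS database ships with the package; every quantitative check
runs on generated data. The generator plants the full cleavage-site
cis-architecture, not just the core: an upstream U-rich element at
−85..−55, AATAAA starting 26-30 nt upstream, CA at the site, the
downstream U-rich stretch at +5..+25, and a GU-rich element at +28..+48.
The auxiliary elements give the signal the ±85-nt footprint real sites
have, so a window shifted by ±25-50 nt genuinely loses part of its
evidence — the mechanism behind position sensitivity. Background
sequence is AT-rich (A = T = 0.35, C = G = 0.15, the approximate
composition of intergenic DNA) with A/T homopolymer tracts of 8-20 nt
scattered at about one per 1.5 kb, because i.i.d. draws underrepresent
homopolymers by orders of magnitude relative to real genomes. Both
choices matter beyond realism: with chance hexamers, T-runs and
homopolymer tracts in the negative class, "signal-like content
anywhere" is not a viable decision rule, and a classifier that never
saw A-runs as negatives would have nothing to ground the
internal-priming check. On a uniform background the discrimination task
is so easy that both training schemes converge to position-agnostic
solutions and the contrast between them disappears; that observation
drove the deviation from a uniform background.

The classifier benchmark trains the reduced architecture (scale 0.125)
on 500 sites x 10 shifted windows + 5,000 negatives, and the fixed
variant on the same 500 sites' centered windows + 500 negatives. Both
variants get the same optimization budget — about 480 Adam updates
(12 epochs of the large corpus vs 160 of the small one, batch 256) with
best-epoch selection — because at equal epoch counts the 10x-smaller
fixed corpus would be undertrained and the comparison would measure
budget, not corpus design. The fixed variant is additionally trained in
five independent repeats whose per-offset true-positive rates are
averaged: its small corpus leaves the optimum genuinely sensitive to
initialization (single-run far-offset TPR ranges roughly 0.1-0.8), and
averaging repeats — standard practice for model comparisons — measures
the training scheme rather than one draw of it. Measured quantities:
held-out AUC on 500 + 500 centered validation windows, and per-offset
true-positive rates on windows shifted in 5-nt steps to ±50. The
shifted model's mean TPR over |offset| in [25, 50] exceeds the fixed
variant's average; both decay toward ±50, as expected when training
shifts are drawn with sd 10 and auxiliary elements leave the window.

Internal-priming rejection is probed by embedding adenine runs of length
8-15 at the center of intergenic windows sampled far from any annotated
site; the classifier should (and does) score >= 90% of them negative.
What these synthetic checks do not show: performance on real sites with
degenerate signals, on non-canonical signal variants the generator never
plants, or at the scale and class imbalance of a real genome — the
printed full-scale accuracies are not reproducible from this package and
are not claimed by it.

## Quantification

Surviving sites are assigned to the transcript of their gene with
maximal footprint overlap (ties to the longest spliced transcript); the
feature is that transcript's exon chain truncated at the cleavage site,
written out as a PAS-based GTF that round-trips through the package's
GTF reader. UMI counting assigns each sense-strand read to the feature
with the largest base-pair overlap; because truncated features of one
gene nest, upstream reads can tie across features, and ties are resolved
toward the feature whose 3' end is nearest the read's 3' end — for
3'-biased chemistry this is the generating feature — then by feature
order. Within a (barcode, feature) pair, distinct UMI strings count once;
no error-aware UMI collapsing is attempted (the upstream protocol leaves
the collapsing method unstated, so the simplest exact-identity contract
is used and stated). Reads lacking either tag are skipped and tallied.
Expression (RPM) over a region is its read count — multi-overlap
counting, sense strand, MAPQ >= 3 — divided by total mapped reads, times
1e6; for a database site the region is the 400 nt upstream of the
annotated cleavage position.

## Evaluation and APA statistics

The enrichment score of a candidate site is
log2((RPM_upstream + 0.1) / (RPM_downstream + 0.1)) over 400-nt windows
(clipped at contig bounds): true 3' boundaries have high upstream and low
downstream coverage. Classifier calls cross-tabulated against
enrichment-defined truth (score >= 2, after an RPM >= 1 expression
filter; cutoffs 1.5-2.5 supported as a sweep) give sensitivity,
specificity and F1 = 2TP/(2TP + FP + FN). ROC curves sweep distinct score
thresholds with tie grouping; the trapezoidal AUC is tested against the
Mann-Whitney rank statistic to 1e-9.

For APA, features of a gene are ordered by strand-oriented distance from
their cleavage site to the annotated gene 3' end; the proximal PAS is
the farthest (shortest 3'UTR), and single-PAS genes are excluded from
usage scoring. Per cell and gene, usage =
log2((CPM_proximal + 1) / (sum CPM_rest + 1)), with CPM over all PAS
features of the cell. A cell's global proximal preference is its mean
usage over expressed multi-PAS genes, Z-scored across scored cells
(sample sd; all zeros when variance is zero). Differential usage between
cell groups reports, per feature, log2 fold change of (mean CPM + 1) —
the CPM scale keeps the +1 from compressing real effects — a two-sided
Wilcoxon rank-sum P (the substitution for the upstream toolkit's default
test), and expressing-cell fractions; significance requires
|logFC| >= 1.2, P <= 0.05 and min.pct >= 0.3 in at least one group (the
one-group reading of an ambiguous threshold). Calibration on simulated
Poisson matrices: null false-flag rate <= 7% at 100 cells/group, >= 90%
power for 4-fold shifts at 200 cells/group (500 features, fixed seeds).
Poly(A)-signal occurrence scans AATAAA, ATTAAA, A[GC]TAAA and AA[GC]AAA
(DNA alphabet) in [−50, +25] around 3' ends, counting each site once;
positional profiles report per-offset motif-start density and base
frequencies over ±100 nt.

## The generator's reference conditions

`sim_config()` defaults define the fixture every end-to-end number is
measured on: 2 chromosomes x 250 kb; 50 genes of 3-5 exons (first exon
400-600 nt so windows upstream of the first site stay inside the
transcript; introns 600-900 nt so artifact pileups fit inside one
intron); 2-3 cleavage sites per gene spaced 900 nt (two 400-nt peaks
overlap by less than half their width, so aggregation cannot merge
distinct sites); ~60 expected reads per site across 200 cells (Poisson
per cell); 90-nt reads; 10-nt UMIs, distinct within each (cell, site)
pair so the distinct-UMI truth table is exact; every site carries the
planted signal; 30% of genes carry a 20-adenine intronic locus — the
scale of run an oligo(dT) primer mis-anneals to — with its own artifact
pileup; PCR duplicates off by default (a geometric
duplicate rate is available and changes no distinct-UMI count). Read 5'
starts are uniform on [site − 400, site − 50] in spliced coordinates —
the geometry that makes the greedy caller's downstream tie-break land
the 3' end at the site.

Problem sizes in the test suite and acceptance script (reduced model,
500-site corpora, the 50-gene fixture, 201-point dip subsample, 200-way
null tables) are the package's reference desk scale: large enough that
every rate being tested is estimated to within a few percent, small
enough to re-run routinely.

## Known limitations

Peak calling assumes 3'-biased, stranded chemistry; unstranded data are
out of scope. The classifier's desk-scale benchmark plants a single
canonical signal and cannot speak to variant-signal sensitivity. UMI
counting does not collapse near-identical UMIs. The dip null is
calibrated against the uniform distribution, the classical but
conservative reference. Downstream single-cell analysis (clustering,
integration, visualization) is deliberately left to the ecosystem
consuming the exported matrix.
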