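---
title: "Classifying cis-regulatory elements from ATAC-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cis-regulatory elements from ATAC-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

ATAC-seq maps accessible chromatin at base-pair resolution, but an
accessibility peak alone does not say *what* the underlying element does.
The same open region could be a promoter, an enhancer, a CTCF-bound
insulator, or something else entirely (transcribed, repressed, or
low-signal chromatin that happens to be open). `atacre` infers that
functional class directly from the ATAC-seq data and the DNA sequence
under each peak, so that a single assay — including aggregated
single-nucleus data — can be annotated without the panel of ChIP-seq
experiments that a ChromHMM segmentation would require.

The signal that makes this possible is structural: paired-end ATAC-seq
fragments record where the Tn5 transposase cut and how long the protected
insert was. Nucleosome-free regions yield short (sub-nucleosomal,
< 147 bp) fragments; positioned nucleosomes yield mono-nucleosomal
(~147–295 bp) fragments; bound transcription factors leave sharp
footprints in the cut-site profile. Promoters, enhancers and insulators
differ systematically in these profiles, and in sequence features such as
the CTCF motif.

# The peak encoding

Each peak is encoded as a 10 × 600 matrix over the 600 bp window centered
on the peak (300 bp each side of the center, where the center is
`floor((start + end) / 2)` — the floor makes even- and odd-length peaks
deterministic).

* **Rows 1–4** — the frequency of observing A, C, G or T in the fragment
  pileup at each position, computed when at least `min_depth = 10` base
  calls are available; below that the column falls back to a one-hot
  encoding of the reference base (all zeros when the reference base is
  N). This is the genotype-aware part of the encoding: an individual's
  alternative allele shows up in the frequencies, not in a fixed
  reference one-hot. A personalized consensus FASTA can also be supplied
  directly.
* **Row 5** — the insert pileup: the number of fragments spanning each
  position. A fragment is the full sequenced insert, 5'-most to 3'-most
  base of the pair.
* **Rows 6–7** — 5' and 3' cut counts per position, Savitzky–Golay
  smoothed (window 15, cubic), which spreads depth-driven spikes over
  adjacent positions.
* **Rows 8–9** — the median insert length of fragments cutting at each
  position (5' and 3' respectively), zero where no fragment cuts, then
  smoothed like rows 6–7.
* **Row 10** — a binary indicator of the original peak interval, which
  disambiguates adjacent peaks sharing a window.

Rows 5–9 are z-standardized per column *across all peaks of a dataset*
(two passes: raw tracks first, then standardization), using the
population standard deviation; zero-variance columns map to 0. The
fitted per-column means and SDs travel with the encoded dataset and are
re-applied verbatim at prediction time — nothing is silently re-fitted.

Design choices worth stating explicitly:

* **Smooth, then standardize.** Smoothing is part of track construction;
  standardization is a dataset-level operation. Doing it in this order
  keeps the standardized columns' moments exact (mean 0, SD 1) by
  construction.
* **Savitzky–Golay order 3.** The polynomial order is not dictated by the
  window size; cubic is the common default and is configurable
  (`smooth_polyorder`). Edge positions take the terminal window's
  polynomial fit evaluated at the edge.
* **No Tn5 +4/−5 shift by default.** The encoder counts cuts at the
  fragment endpoints as aligned. The conventional transposase offset is
  available as `tn5_shift = c(4L, -5L)` but is off unless requested.
* **Fragment spans, not read coverage, in row 5.** An "insert" is the
  sequenced fragment; both reads of a pair delimit one insert.
* **Depth counts A/C/G/T calls only.** N calls and positions outside any
  fragment do not count toward the `min_depth` test.
* **Median rows smear.** Smoothing a median track mixes the zero fill at
  cut-free positions into neighboring values; this is a known artifact
  of smoothing order statistics and is accepted for consistency with the
  cut-count rows.

Base calls are modeled as: each fragment contributes the reference base
at every covered position unless it carries a recorded substitution
there. From BAM input, substitutions are recovered from read-vs-reference
mismatches; the plain fragments-BED dialect carries them in a `variants`
column (`pos:base;...`, 0-based). The two routes produce identical
matrices, which the test suite asserts.

# The auxiliary feature vector

A second branch of the classifier consumes 19 manually engineered
features per peak. The length-19 contract and the branch interface are
fixed; the membership is a configurable registry. The default registry
draws on the feature families the method depends on: signed distance to
the nearest TSS, peak length, peak-caller −log10 q-value, fragment count,
insert-size mean/SD, sub- and mono-nucleosomal fractions, 5'/3' cut
asymmetry, GC fraction, CpG count, CTCF motif count (IUPAC consensus
`CCGCGNGGNGGCAG`, matched on both strands, overlapping hits counted,
N never matches), four further motif counts (TATA, CAAT, GC-box, AP-1 by
default), mean conservation (0 when no track is supplied), summit offset
fraction, and duplicate fraction. Missing optional annotations take
documented neutral values (TSS distance 1e6, conservation 0, q-value 0,
summit fraction 0.5) so the vector never shortens. Features are
z-standardized with statistics fitted on the training split and stored in
the model.

# Ground truth

ChromHMM-style segmentations assign a state label to every interval; the
package merges states into the four classes with built-in tables for the
public 18-state scheme and the EndoC beta-cell scheme, plus a `custom`
scheme for in-house models. Neither built-in scheme has an insulator
state — a documented labeling limitation of those references; the
synthetic scheme used in tests adds one.

A peak is labeled only when a single class covers at least 90% of the
peak's length (exact interval-intersection sums; the threshold is
inclusive, and the denominator is the peak length, not the
segmentation-covered length — the stricter and simpler reading when the
segmentation has gaps). Ambiguous peaks are excluded. The classes are
merged *before* the unanimity test, so two adjacent enhancer states count
together.

Chromosome-level splits prevent sequence memorization: chromosomes 2 and
10 are validation, 3 and 11 are test, the remaining 18 autosomes train;
X, Y and M are excluded. For consensus-peak analyses the "other" class
can be augmented with consensus regions not called in the sample, capped
so augmented examples are at most 25% of all "other" examples
(`n ≤ floor(P · cap / (1 − cap))`), drawn uniformly with a seed.

# The classifier

The deep branch treats the encoding as a 1D sequence of 600 positions
with 10 channels (the only orientation in which a 1D convolution over a
10 × 600 matrix is meaningful). The default architecture is four blocks
of

    conv(k = 19, stride 1) → batch norm → conv(k = 19, stride 1)
    → max-pool(2) → batch norm

with 256 filters in the first two blocks and 512 in the last two,
followed by a 2048-unit dense head. ReLU follows each convolution and
dense layer (the standard choice; a linear stack would collapse).
Convolutions use zero 'same' padding so the position axis shrinks only at
the pools (600 → 300 → 150 → 75 → 37); max-pool stride equals the pool
size. The auxiliary branch is a dense 2048 head over the 19 features. The
two heads are concatenated into a 512-unit joint dense layer and a 4-way
softmax output.

Training is staged because the two branches overfit at different rates:
each branch first trains separately with its own temporary output layer,
monitoring validation loss (default 20 epochs, early-stopping patience 5,
best weights kept); then the concatenated model trains end to end for a
final round. The joint stage updates *all* parameters — branch freezing
is a possible alternative reading, but fine-tuning everything is the
default here and is flagged as an interpretation. Batches of 32, Adam at
learning rate 0.001, He initialization. Given a seed, training is
deterministic; batch normalization uses stored running moments at
prediction time, so predictions are independent of batch composition and
order.

The engine itself (im2col convolutions with a C++ kernel, batch norm,
pooling, dense layers, softmax cross-entropy, Adam) lives inside the
package, written against base R matrices and BLAS.

The hyperparameter menus explored during tuning (kernel ∈ {9, 11, 19,
21}, blocks ∈ {3, 4, 5}, dense ∈ {1024, 2048, 4096}, filters ∈ {32, 128,
256}) are carried in `model_config()$tuning_grid` as configuration space;
no automated search loop is shipped.

**Problem sizes in the test suite.** The tests and the acceptance script
train a scaled-down configuration — 2 blocks with 16/32 filters, 64/32
dense units, 3 branch + 2 joint epochs — on the synthetic fixture of
2000 training, 400 validation and 400 test peaks. This is the package's
chosen experiment size for a single CPU; the architecture family is
identical to the default, only widths and depth shrink. On that fixture
the staged model reaches held-out accuracy ≥ 0.90 (typically ≈ 1.0,
because the archetypes are well separated; see the caveat below).

# Genotype-modulated gain/loss of activity

Per-sample regulatory activity at a locus is summarized as the sum of the
promoter and enhancer probabilities. For each locus with genotype data,
the point-biserial correlation (Pearson correlation against a 0/1 group
coding, `t = r·sqrt((n−2)/(1−r²))`) is evaluated for every pair of
genotype groups present among ref/ref, ref/alt and alt/alt, coding the
higher-alt-dosage group as 1; the pairing with maximum |r| is kept (ties
broken toward the larger combined n), *before* any significance
threshold. The reported p-value is one-tailed in the direction of the
observed correlation — the minimum over the two orientations, which is
exactly the "separate negative and positive correlations, each with a
one-tailed p" construction. The classical pooled t transform is used (a
Welch-style variant is conceivable but not the standard point-biserial
definition). Loci with p < 0.01 are called `loss` (r < 0) or `gain`
(r > 0).

Concordance with reporter assays: predicted-loss loci should have MPRA
log fold changes below zero and predicted-gain loci above zero (one-sided
one-sample t-tests per group), and the two groups should differ
(two-sided Mann–Whitney U). Degenerate groups (fewer than two values, or
constant) report NA rather than failing.

# The synthetic generator

Every module is testable without downloads because the package generates
its own data, all of it a pure function of (config, seed):

* **Reference sequence** — i.i.d. bases at a target GC (41% default).
* **Class archetypes** — each class has a fragment model: expected depth
  (promoter 400, enhancer 250, insulator 200, other 80 fragments),
  positional spread around the center (80 / 60 / 30 / 150 bp — the
  insulator footprint is sharpest, "other" is diffuse), and a
  two-component lognormal insert-size mixture (sub-nucleosomal mode
  ~70–100 bp, mono-nucleosomal ~200 bp) with class-specific weights
  (0.80 / 0.60 / 0.75 / 0.30 sub-nucleosomal). Insulator loci plant the
  CTCF consensus in the reference at the center; promoter loci register
  a TSS. Peak q-values are drawn from class-typical ranges.
* **Segmentations** — each locus is covered by a state mapping to its
  planted class, background by a quiescent state, so labeling round-trips
  exactly.
* **Genotyped cohorts** — 19 samples by default (a typical islet cohort
  size), alt-allele frequency 0.3, per-locus fragment counts Poisson with
  mean shifted by `direction × effect_size × sqrt(base_depth)` per alt
  allele — so `effect_size` is calibrated in population SDs of the null
  count — and alt-base substitution in fragments covering the SNP with
  probability dosage/2. Planted directions alternate gain/loss, and a
  concordant MPRA-style log fold change (mean ±0.8, SD 0.4) is drawn per
  locus. The gain/loss screen in the tests scores loci by normalized
  fragment depth, which is what the planted effect manipulates; the
  smaller end-to-end test exercises probability-based scoring.

What the generator does **not** emulate: GC bias, mappability, chimeric
fragments, cross-class ambiguity (real enhancers and promoters overlap in
their signal distributions far more than these archetypes do), label
noise in the segmentation, or batch effects between samples. Passing the
recovery tests therefore demonstrates that the pipeline is implemented
correctly — encodings faithful, training functional, screens calibrated —
not that real-data performance matches; near-perfect synthetic accuracy
is expected and is a property of the fixture, not a performance claim.

# Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package;
  1-based formats convert at the boundary.
* Population (not sample) SD in all standardization; zero-variance
  columns/features standardize to 0.
* Average precision uses the precision–recall step integral with tied
  scores treated as one threshold step (deterministic across library
  versions); ROC AUC is the rank statistic with mid-ranks for ties and is
  reported NA for a degenerate class; multiclass MCC is the generalized
  (Gorodkin) confusion-matrix form, 0 when the denominator vanishes.
* Fisher's exact test reports the two-sided exact p and the sample
  cross-product odds ratio with Haldane correction (+0.5 per cell) when
  any cell is zero.
* Constant scores in the point-biserial give r = 0, p = 0.5; |r| = 1
  gives p = 0.
* Naive baseline q-value comparisons accept raw q or −log10 q with an
  explicit flag; raw q is canonical internally.
* Max-pool keeps ties to the first (left) element; odd-length inputs drop
  the trailing position.

# Known limitations

* The built-in public label schemes carry no insulator state; models
  evaluated against them cannot be scored on insulators.
* The exact membership of the original 24-feature set from which the
  19-feature auxiliary vector descends is not enumerated here; the
  registry is an explicit, configurable stand-in with the same interface.
* Single-cell data is encoded only after aggregation to pseudo-bulk
  fragments; per-cell classification is out of scope.
* Training the full-width default architecture (256/512 filters, 2048
  dense) is a GPU-scale undertaking; this package trains it correctly but
  slowly, and its tests exercise scaled-down widths.
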