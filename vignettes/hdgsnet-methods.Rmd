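---
title: "Methods: sequence-based nucleosome occupancy prediction with hdgsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based nucleosome occupancy prediction with hdgsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A nucleosome wraps ~147 bp of DNA around a histone octamer, and where
nucleosomes sit is partly written in the DNA itself: bendable, GC-rich
sequence favours wrapping, while rigid AT-rich runs (AA/TT/AT/TA
dinucleotides) resist it. MNase-seq maps of nucleosome occupancy give a
per-base, population-averaged coverage signal. `hdgsnet` implements a
sequence-to-occupancy regression at single-base resolution: given only the
147-bp window of DNA centred on a position, predict its normalized
occupancy.

## Data model and normalization

Occupancy tracks are carried per base in 0-based coordinates. The **dMean**
transform divides every per-base value by the mean over all covered bases of
all chromosomes jointly, so the genome-wide average is exactly 1; values are
non-negative and the genome mean is an interpretable unit. Coverage gaps
(and the first/last 73 bases, which have no full window) are zero-filled,
flagged uncovered, excluded from the mean, and reported. The 1-based
fixedStep WIG dialect is converted at the boundary of the package; all
internal coordinates are 0-based half-open.

## Stratified site screening

Occupancy is strongly left-skewed: the median sits near the lower quartile
and a thin right tail carries the strongest positioning signal. Sites are
therefore screened by boxplot statistics (type-7 quantiles): positions above
`Q3 + 1.5*IQR` form the high-occupancy stratum, sampled at 1:3; the rest are
sampled at 1:30. Two "1:k" mechanisms are provided, since the sampling
mechanism itself is a design choice: *systematic* (every k-th eligible
position in coordinate order; exactly `ceiling(n/k)` sites, fully
reproducible and the default) and seeded *Bernoulli* (keep with probability
1/k). Thresholds default to per-chromosome statistics, with a global option.
Train/test partitions are made leakage-free by construction: whole-chromosome
holdout or a seeded disjoint split of coordinates. Known-bad regions are
removed with an explicit blacklist; no automated anomaly detector is
included, because deciding that a segment is artifactual is a data-curation
judgement this package does not try to automate.

## Encoding

Each site contributes the 147-bp window centred on it. The window is encoded
as overlapping **dinucleotides**: column *j* is the one-hot indicator of the
dinucleotide at positions (*j*, *j*+1), rows ordered lexicographically
AA, AC, ..., TT, giving a binary 16 x 146 matrix whose columns each sum to 1.
Dinucleotides are the natural unit because the bending anisotropy that
positions nucleosomes is a property of base *steps*, not single bases. The
overlap makes the code invertible (`decode_onehot()` is exact). For
minus-strand sites the window is reverse-complemented (5'->3' on the
annotated strand); plain complementation without reversal was considered and
rejected as it does not correspond to reading the opposite strand. Windows
containing N are skipped and reported rather than imputed: a one-hot code
has no honest N channel. The window label is the dMean value at the centre
base.

## Architecture

The network treats the 16 x 146 matrix as a height-16, width-146, 1-channel
image in which all kernels are 1 x K: convolution runs along sequence
position only, so the 16 dinucleotide rows pass unmixed to the flatten
stage. Three building blocks are combined:

* **Gated convolution (GC)** — `Y = (X*W + b) * sigmoid(X*V + c)`, an
  elementwise product of a linear feature path and a sigmoid gate path. The
  gate is the branch nonlinearity; no extra activation is added.
* **Dilated convolution (DC)** — taps spaced `l` positions apart
  (`sum_y F(x + l*y) k(y)`), enlarging the receptive field with no extra
  parameters; DC branches are followed by ReLU.
* **Depthwise-separable convolution (DSC)** — a per-channel 1 x K depthwise
  stage (no bias) followed by a 1 x 1 pointwise mix (with bias);
  `K*C_in + C_in*C_out` parameters instead of `K*C_in*C_out`.

The reference configuration stacks two levels of **Module A** (five parallel
branches: 1x1, 1x3, 1x7 GC; 1x7 DC at rate 3; 1x11 DC at rate 5; 128
channels each, concatenated to 640), **Module B** (four branches, 512
channels), and **Module C** (three branches, 64 channels each to 192, with
the K > 1 branches depthwise-separable; a gated separable branch duplicates
both stages for its gate path). Every module ends with channel-axis batch
normalization, 40% dropout, and a 1 x 3 stride-3 max pool; the input passes
a global batch normalization first. All convolutions are same-padded, so the
width changes only at the pools: 146 -> 48 -> 16 -> 5 -> 1. The final
16 x 1 x 192 tensor flattens to 3072 features and feeds a fully connected
256 -> 32 -> 1 head — ReLU output for regression (occupancy is
non-negative), sigmoid for classification. This wiring is the one
configuration consistent with all four printed stage shapes and the
~6.6-million-parameter budget; the pooling placement (after *each* Module A
level) and the location of the separable stages (Module C's K > 1 branches)
were the genuinely open choices, and both are isolated behind the
declarative `hdgs_config()` so alternatives remain expressible. The total
trainable parameter count of the reference configuration is **6,628,227**
(`count_parameters()`, cross-checked in the tests against an independent
closed-form per-layer sum).

`hdgs_config(scale = k)` divides every channel width (branch channels and
the fully connected hidden widths) by `k`, preserving the width trace; the
`scale = 8` model (~104k parameters) is the desk-scale configuration used in
the test suite.

## Implementation notes

The network runs on the CPU through a compiled float32 engine
(RcppArmadillo). Activations are stored channel x (width x lanes) with
position-major columns, which turns every dilation tap of a same-padded
1 x K convolution into one contiguous BLAS `sgemm` call; the 16 input rows
are independent convolution lanes, exactly equivalent to 1 x K kernels on
the 16 x W x C tensor. The gate sigmoid uses a polynomial exponential
(~1e-6 relative error). All randomness (initialization, shuffling, dropout)
comes from a dedicated counter-based generator seeded from the configs, so
identical seeds give identical histories and predictions on the same
platform; training is single-threaded. Numerical conventions: Glorot-uniform
initialization; batch-norm epsilon 1e-3 and momentum 0.9; Adam with
beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7; max-pool ties resolve to the
leftmost position; zero padding value.

## Training

Adam at initial learning rate 1e-4, MSE loss with MAE as the monitored
metric (binary cross-entropy/accuracy for the classification head), batch
size 64, and a 3:1:1 train/validation/test split (largest-remainder
rounding, seeded shuffle). The learning-rate schedule and checkpoint policy
are stated choices: reduce-on-plateau with factor 0.5, patience 5, floor
1e-6, monitoring validation loss; "best model" means minimum validation
loss, and those weights are restored after the last epoch. A non-finite
loss aborts with a diagnostic rather than continuing silently. The
regression head's output bias starts at 1 — the dMean genome mean — so the
ReLU output is live from the first update (an all-negative start has zero
gradient and would never recover).

## The synthetic generator

Real MNase maps are not shippable nor desk-scale, so the package carries a
generator that emulates the statistical structure the method relies on,
with fixed defaults that are the package's study conditions:

* **Genome**: blocks of geometric length (mean 500 bp) with block GC drawn
  from Beta(2,2) rescaled to [0.2, 0.8] — yeast-like isochore-ish
  heterogeneity so that windows differ in composition.
* **Occupancy**: for each full-window centre,
  `s = alpha*f_GC - beta*f_AT` over the window's 146 dinucleotides
  (frequencies of GG/CC/GC/CG and AA/TT/AT/TA), and
  `occupancy = exp(s + eps)` with `eps ~ N(0, 0.3^2)`, optionally Poisson
  read sampling, then dMean. The lognormal form reproduces the left-skewed,
  non-negative occupancy distribution (median below mean) and makes GC/AT
  composition the ground-truth driver with a known effect direction. The
  default weights are `alpha = beta = 2`: this calibration makes the
  normalized track quantitatively resemble a real dMean map — values
  spanning roughly 0–4 around the genome mean of 1, and fewer than 5% of
  positions above the boxplot outlier threshold on a 200-kb genome. Larger
  weights (e.g. 6) blow the dynamic range up to ~40 genome-means and push
  the outlier fraction above 10%, which no real map shows; they remain
  available as explicit arguments.
* **TSS**: uniform positions with ±1000 bp clearance and random strand,
  feeding the 10-bp-grid window builder (201 centres per interior TSS,
  endpoints included).

The generator is test infrastructure with a declared model, not a claim
about chromatin biology. Passing the recovery experiment shows the
pipeline and optimizer can learn a composition-driven occupancy signal from
encoded sequence alone; it does not show the architecture captures real
positional periodicity (the synthetic signal has none), nor MNase digestion
bias, linker phasing, or species differences.

## Desk-scale problem sizes

The test suite exercises the full pipeline end to end at sizes chosen for a
single CPU: the learning-recovery experiment draws a 500-kb synthetic
genome, screens it 1:3/1:30 to 20,000 sites, trains the `scale = 8` model
for 3 epochs at the default configuration, and requires held-out Pearson
r >= 0.8 from the best-validation checkpoint; k-means occupancy groups on
the same data must show
GC-type dinucleotide frequency increasing monotonically from the low to the
high group, and AT-type decreasing. The reference `scale = 1` model is
built and run forward in the tests (shape trace and parameter count) but
never trained there; the training harness supports full-scale runs
unchanged for users with real data and patience.

## Evaluation and sequence statistics

Predictions are compared per chromosome by Pearson correlation (the
summary is the unweighted mean over non-excluded chromosomes, matching how
genome-wide tables are usually reported; a site-weighted variant is a flag),
plus MAE and R^2 over pooled sites. Occupancy-dependent composition
analyses mirror the standard battery: quartile split (strictly above Q3 vs
strictly below Q1, middle excluded), 1-D k-means with k = 3 relabelled by
descending centre, and descending deciles G1..G10 (ties broken by original
index). Groups feed pooled mono-/dinucleotide frequency tables and the
16 x 146 positional frequency matrix whose columns sum to 1. The enrichment
test is a two-sided, continuity-uncorrected two-proportion z-test — a
declared stand-in, isolated so another test can be swapped in.

## Known limitations

* The on-disk dataset container uses R serialization (RDS) with validated
  fields rather than HDF5; the accessor API (`write_dataset()` /
  `read_dataset()`) hides the carrier.
* Only bedGraph and fixedStep WIG tracks are read; BigWig/BAM ingestion and
  read alignment are out of scope.
* The synthetic generator has no nucleosome phasing, no digestion bias and
  no in-vivo remodelling effects; conclusions about real chromatin require
  real maps.
* Chromosome-scale anomaly detection is deliberately manual (blacklist
  files).
* Training is CPU-bound; the reference model at full scale is supported but
  slow (hours per epoch on large site sets), which is why the desk-scale
  configuration exists.
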