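---
title: "Calling candidate functional TF motifs in enhancers"
author: "enhancerlift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling candidate functional TF motifs in enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A position weight matrix (PWM) scan of an enhancer set returns every
sequence that merely *resembles* a transcription-factor binding site; most
such matches carry no regulatory function. `enhancerlift` implements a
two-evidence procedure for prioritising motif matches that a sequence-based
enhancer classifier actually *uses*: a match is called functional only if

1. its PWM log-odds score reaches a cutoff calibrated to an empirical
   false-positive rate (FPR) below 0.2% per scanned element, **and**
2. at least 3 of its footprint positions fall among the top 20% (top 60 of
   300 bp) most important nucleotides of its window, as measured by
   per-nucleotide attribution of a trained enhancer classifier.

The package provides the whole chain — labelled dataset construction from
peaks and histone-mark tag counts, classifier training, attribution,
cutoff calibration, scanning, and the final conjunction — plus a
synthetic-data generator with known planted ground truth, so that every
stage (and the pipeline end to end) is testable without any external data.

## Dataset construction

Candidate elements arrive as peak intervals with a histone-acetylation
(H3K27ac-style) tag count per peak. Positives are peaks with at least
`min_tag_count = 32` tags, off the sex chromosomes, standardised to a
300 bp window centred on the peak midpoint (summit positions are not
assumed to be available). Negatives are equally many random genomic
windows, drawn so that each lands in the same 2%-wide GC-fraction bin as
its paired positive, overlapping no positive window. Splits are by
chromosome only — `chr8` is held out for validation and `chr9` for testing
— which prevents any positional leakage between splits.

Two conventions worth noting:

* **GC matching is at bin resolution.** Per-pair binned matching makes the
  positive and negative GC histograms identical bin for bin; within a bin
  the two distributions may differ slightly. Tests therefore assert exact
  per-bin equality (the guarantee the design gives), not a raw two-sample
  KS bound.
* **Coordinates.** All in-memory intervals are 1-based inclusive, as in
  `IRanges`; files on disk use BED conventions (0-based half-open), and
  the readers/writers convert.

## The classifier

The classifier is a small convolutional network over one-hot encoded
sequence (columns A, C, G, T; `N` encodes as the uniform 0.25 row):
32 filters of width 12, ReLU, max-pool of width 8, then 32 filters of
width 4, ReLU, and a **global** max-pool feeding a single sigmoid unit.
Training minimises binary cross-entropy with Adam (learning rate 5e-3,
batch 16, decoupled weight decay 1e-4), up to 50 epochs with early
stopping (patience 5) on validation auROC; the parameters of the best
validation epoch are returned.

The global second pool is deliberate. At a few hundred examples per class,
architectures that pass positional feature maps to the read-out can reach
low training loss by memorising window-specific features while validation
auROC stays near chance; a translation-invariant read-out (per-channel
maxima only) forces the filters to encode recurring sequence features —
motifs — and made training robust across seeds in our benchmarks
(test auROC 0.97–0.99 at the default synthetic scale).

Two further design points:

* **No reverse-complement augmentation or weight tying.** Strands are
  handled at interpretation time (below). An optional
  reverse-complement-equivariant first layer (`rc_equivariant`) is
  provided, but it *worsened* attribution of non-palindromic motifs in our
  development benchmarks and is off by default.
* **Ensembling.** When two motifs co-occur in most active elements, either
  one suffices to separate the classes, so which one a single network
  learns is a lottery of the initialisation — and the ignored motif then
  receives no attribution. `run_pipeline()` therefore trains an ensemble
  (default 4 members differing only in derived seeds). Predictions are
  member means; the importance track of a window is the elementwise
  maximum of the member tracks, which retains every feature that any
  member's fit discovered. Member means of the signed scores are also
  available and satisfy summation-to-delta against the ensemble-mean
  output exactly.

`auroc()` implements the rank-based (midrank-tied) estimator, equal to the
brute-force pair-concordance probability; the test suite asserts that
equality on random instances.

## Per-nucleotide attribution

`importance_scores()` propagates DeepLIFT-style multipliers from the
output probability to the input against a uniform reference (0.25 at
every base, passed through the network as-is):

* linear layers (convolutions, dense): chain-rule multipliers — exactly
  delta-preserving because biases cancel in differences;
* ReLU and the output sigmoid: the rescale rule
  `m = delta_out / delta_in`, with the derivative as the
  vanishing-denominator fallback;
* max-pool: the pooled delta is routed entirely to the in-window input
  with the largest |delta|, with multiplier `delta_out / delta_in`. We do
  not use the plain gradient path (routing to the actual argmax) because
  it breaks the summation-to-delta identity whenever the actual and
  reference argmax differ; the chosen routing preserves it exactly.

The per-position score is the sum of the four channel contributions at
that position. With a uniform reference the off-base channels (input 0,
reference 0.25) carry non-zero contributions, so summing the channels is
the only per-position collapse for which
`sum(scores) = p(x) − p(reference)` holds; the suite checks this identity
to 1e-3 on random windows (it holds to ~1e-15).

A `grad_x_input` backend (ordinary input gradient times input difference)
is available as a fallback and is flagged in the result's `method`
attribute; it is exempt from the summation guarantee.

Strands: scores are computed for the window and for its reverse
complement, the latter re-aligned by index reversal, and the final track
is the elementwise absolute maximum — making the track invariant under
reverse-complementing the input. `top_fraction_positions()` then takes the
`floor(0.2 * L)` highest-scoring positions (60 for L = 300), breaking ties
by larger score first, then smaller coordinate.

## PWM scanning and FPR calibration

JASPAR-format matrices are converted to frequencies with a pseudocount
mass of 1% of each column total (split by the background composition) and
to log-odds `log2(freq / background)` against a uniform background — the
scoring function itself (log-odds vs probability) is a package choice, as
is the background. A window of motif width scores as the sum of the
log-odds of its observed bases; `N` makes a window unscorable and it is
skipped.

The cutoff is calibrated empirically: every background window is scored at
every offset on both strands; a window passes if any position on either
strand reaches the candidate cutoff; the returned cutoff is the smallest
observed per-window best score for which the fraction of passing windows
is below the target (default 0.2%), and the achieved FPR is recorded. At
least `10 / target_fpr` background windows are required so the estimate is
meaningful. The FPR unit is *fraction of scanned elements containing at
least one hit* — matching how elements are filtered downstream.
(`target_fpr = 1` is the documented vacuous bound: the minimum observed
score is returned and everything passes.)

The pipeline's calibration background is drawn by the same GC-matched
sampler as the training negatives (6000 windows by default), avoiding all
candidate peaks — windows overlapping motif-carrying peaks would
contaminate the null and inflate the cutoff. For rare extreme GC bins the
background sampler falls back, after its retry cap, to the draw closest to
the requested bin centre rather than aborting; the training-negative
sampler instead reports an error naming the infeasible bin.

## Functional calls and recovery

`scan_pwm()` reports every offset–strand match at or above the cutoff
(inclusive, matching the calibration convention) in forward-strand
coordinates. `call_functional()` counts, for each match, its footprint
positions inside the window's top-importance set — strand-agnostically,
since the track is strand-symmetric — and flags the match functional when
the count reaches `min_overlap = 3`. Overlapping matches are all reported;
no merging is done.

On synthetic data, `recovery_report()` scores functional calls against the
planted truth: a call is a true positive if a truth interval of the same
motif overlaps it (tolerance 0 = at least one shared base), and a truth
instance is recovered if any functional call of its motif overlaps it.
The pipeline restricts truth to instances inside the analysed positive
windows: plants in peaks that the tag filter removed are upstream of the
motif-calling stage being validated. With no calls, precision is reported
as 0 with `precision_defined = FALSE`.

## What the generator emulates — and what it does not

`generate_genome()` draws i.i.d. bases at a configurable GC content
(default 0.41); `plant_enhancers()` places non-overlapping peaks
(rejection sampling with a deterministic failure cap), plants one
column-sampled instance per PWM per active peak at a uniformly random
offset and strand, and draws per-peak tag counts from a negative binomial
(active mean 100, inactive mean 8, dispersion 0.25 — chosen so that the
32-tag cutoff retains almost all active and almost no inactive peaks,
which is what the cutoff is for). The default scale is ten 100 kb
autosomes plus short sex chromosomes, 700 active and 700 inactive peaks.

Real genomes are not i.i.d.: repeats, CpG islands and composition
autocorrelation give real PWM score nulls heavier tails, and real
enhancers carry heterogeneous motif grammars rather than exactly one
instance of each motif. Passing tests on this generator therefore
demonstrate the *correctness of the procedure* (calibration bounds hold,
the conjunction is enforced, planted signal is recoverable), not expected
field performance on any particular genome. One realistic effect the
generator does reproduce: the empirical per-window FPR cutoff lands near
the best background sites that exist in the finite genome, so
column-sampled instances in the lower tail of the PWM's own score
distribution fall below it — recovery of planted instances is bounded by
that tail (~0.6–0.8 of instances pass the calibrated cutoff at the
default conditions), exactly as weak genuine sites are missed in real
scans.

## Numerical and reproducibility choices

* One global pipeline seed; each stage's seed is derived as a hash of the
  seed and the stage name, so editing one stage's configuration never
  reshuffles another stage's randomness.
* Training is deterministic for a fixed seed and single-threaded BLAS;
  the deterministic contract is asserted in the tests.
* Rescale-rule denominators below 1e-9 (and max-pool deltas below 1e-12)
  fall back to derivative/zero multipliers; both guards only activate
  where the corresponding contribution vanishes anyway.
* Degenerate inputs: windows with more than 10% `N` are rejected on both
  sides of the dataset; unscorable (N-containing) scan offsets are
  skipped; single-class training, validation or test splits are errors.
* Problem sizes in the test suite (280 + 280 peaks for the shared unit
  fixture; 700 + 700 peaks, 6000 calibration windows, 4-member ensemble
  for the end-to-end conditions) were chosen as the smallest at which
  training is reliably stable across seeds.

## Known limitations

* The desk-scale classifier stands in for a genome-scale pretrained
  model; its absolute auROC on real data is not comparable to published
  fine-tuned models, and the package makes no claim about it.
* Calibration is empirical only; no analytic p-values, and no
  higher-order (dinucleotide) background models.
* The attribution backends cover exactly the layer set of the built-in
  architecture (conv, ReLU, max-pool, dense, sigmoid).
* `recovery_report()` requires planted ground truth and is meaningful on
  synthetic data only.
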