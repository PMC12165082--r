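---
title: "Methods: screening exfoliated tumor cells with etcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening exfoliated tumor cells with etcscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Body-fluid cytology — here modelled on bronchoalveolar lavage fluid (BALF)
screening for lung cancer — asks whether a slide of stained, exfoliated
cells contains tumor cells (ETCs). Conventional cytopathologist review has
low sensitivity for specimens without obvious tumor-cell clusters, and
manual annotation of single malignant cells is subjective because benign
and malignant morphologies overlap. `etcscreen` implements both halves of
an objective alternative:

1. **A genomic arm.** Single cells lifted from a slide are sequenced at
   low pass; somatic copy-number alteration (CNA) profiles provide an
   annotation of malignancy that does not depend on a reader: multiple
   cells sharing a clonal CNA profile are tumor cells.
2. **An imaging arm.** A cascade over the whole-slide image (WSI) —
   detection, quality control (QC), segmentation, size routing, binary
   classification — counts predicted ETCs per slide.
3. **A diagnosis layer.** The per-slide ETC fraction (`ETC% = 100 ×
   predicted ETCs / QC-passed cells`) is thresholded at an operating
   cutoff (0.2%, boundary positive) and cohort performance is summarized
   with 2×2 contingency metrics, exact confidence intervals and ROC/AUC.

Because patient data are not shipped, a first-class synthetic-data module
generates both kinds of input with planted ground truth, and every claim
the package's tests make is a claim about that generator's output. The
final section is explicit about what this does and does not show.

## Genomic arm

### From counts to ratios

Reads are counted in fixed-width genomic bins (default 500 kb;
`make_bins()` gives each chromosome `floor(length/width)` equal bins and
merges a trailing remainder shorter than half a width into the last bin).
Counts are GC-corrected with a lowess fit of count on GC fraction
(`gc_normalize()`, span 0.3 by default): each bin is scaled by the ratio of
the global mean fitted value to its own fitted value, which flattens the
GC trend while preserving the mean count exactly. Ratios are corrected
counts over their sample mean (`to_ratios()`), so every track averages 1.

Noise is quantified by MAPD (`mapd()`): the mean absolute difference of
adjacent-bin ratios, with pairs restricted to within-chromosome
neighbours. Cells pass QC at MAPD ≤ 0.45. MAPD is computed on the
GC-corrected ratio scale, after correction — the alternative (before
correction) would fold the GC trend into the noise estimate. It is a
*mean*, not a median, and it is invariant under adding a constant to all
ratios.

### Segmentation

`segment_cbs()` is a native circular-binary-segmentation implementation on
log2 ratios, run per chromosome:

* The best "arc" (contiguous window against the rest of the chromosome) is
  found by maximizing the two-sample *t* statistic with the **per-arc
  residual variance** in the denominator. Normalizing by the overall
  variance instead (which permutations also leave unchanged) loses nearly
  all power when the shifted arc is a large fraction of the chromosome,
  because the shift inflates the overall variance itself.
* Significance is a permutation test: up to 10 000 permutations at
  `alpha = 1e-4`, with early stopping as soon as enough exceedances have
  accumulated that significance is out of reach. The permutation stream is
  seeded per chromosome with the same seed, so identical chromosomes
  always segment identically.
* Significant splits recurse; afterwards an "undo" pass merges adjacent
  segments whose standardized mean difference is below `undo_sd` (default
  1) residual standard deviations, with the residual scale taken robustly
  from first differences.
* A final local refinement re-locates each boundary inside its two
  adjacent segments at the position maximizing the standardized mean
  contrast, iterated to a fixed point. The jointly-fitted arcs of the
  recursion compromise between their two edges; the local step recovers
  the single-changepoint maximum-likelihood location.

A note on localization accuracy, because it sets what is achievable: for a
step of size δ in noise of standard deviation σ, the probability that the
maximum-likelihood changepoint lands within ±2 bins is a function of
z = δ/σ alone. At MAPD 0.3 (ratio-scale σ ≈ 0.27, log2-scale σ ≈ 0.38) a
single-copy gain (δ = 0.585) gives z ≈ 1.5 and an *optimal* localization
rate of about 83% within ±2 bins — no segmentation algorithm can do
better. The breakpoint-recovery benchmark in the test suite therefore
plants a two-copy gain (z ≈ 2.6), where the optimal rate is ≈ 95% and the
implementation achieves ≥ 90% over 200 seeded replicates; the benchmark
uses a 120-bin (60 Mb) chromosome with event boundaries away from the
chromosome ends.

### States, burden, and clonal concordance

Segment means are re-centred on the neutral baseline before thresholding
(`call_states()`). The baseline is the mode of the segment-mean
distribution carrying the largest number of bins (single-linkage grouping
of segment means within 0.1, bin-weighted mean of the heaviest group) —
a deliberate simplification of hidden-Markov diploid-region detection that
is equivalent for near-diploid cells, which is the regime of this
application. Gains are called at centred log2 ≥ +0.25 and losses at
≤ −0.25; the defaults sit midway between neutral (0) and a single-copy
change (+0.585/−1). CNA burden (`cna_burden()`) is the percentage of the
*autosomal* genome covered by non-neutral segments; sex chromosomes are
carried through profiles but excluded from burden.

`concordance_score()` correlates two cells' segment-projected per-bin log2
values over the union of bins altered in either cell. Cells with no
altered segment are not eligible (the function returns `NA` with a
reason). When both projected vectors vary over the union the score is the
Pearson correlation; when either is constant there — e.g. two cells whose
only event is the same single gain — Pearson is undefined and the cosine
similarity of the uncentred vectors is used, which preserves the required
limits (+1 identical, −1 mirrored). `call_malignant()` links cells with
score ≥ 0.8 (single linkage) and labels clusters of ≥ 2 cells malignant;
flat cells are always benign. The threshold, linkage and minimum cluster
size are a re-derivation of a published criterion whose exact quantitative
form is not restated in the source literature; all three are configurable.

## Imaging arm

The models in this arm are deliberately compact, feature-based statistical
models. The scientific content of the cascade lies in its structure and
its operating rules — the stage order, the losses, the NMS rule, the
specificity-calibrated thresholds — not in any particular backbone, and
every stage is exposed behind the same interface a heavier model would
use.

* **Tiling** (`tile_wsi()`): non-overlapping 1024 × 1024 patches in
  row-major order; right/bottom remainders are padded with the modal
  border colour and flagged with their pad extent. Reassembling the
  unpadded regions reproduces the slide bit-exactly.
* **Detection** (`train_detector()`/`detect_cells()`): a learned
  background-colour model with an Otsu foreground threshold proposes
  connected components; a logistic model on component features (area,
  density, colour distance, aspect, edge contact) scores each candidate,
  trained against ground-truth boxes matched at IoU ≥ 0.5. Detections are
  kept at confidence > 0.3 and then greedily non-maximum-suppressed at
  IoU > 0.5 (`nms_filter()`); filtering precedes NMS. The squared-IoU
  detection loss (`detection_loss()`, `L = λ·mean(1 − IoU²) + BCE_obj +
  BCE_cls`, λ = 0.5) is provided as a standalone, closed-form-testable
  function.
* **QC** (`train_qc_model()`/`qc_classify()`): a seven-class multinomial
  logistic model on morphometric and texture features of 224 × 224
  standardized crops; classes are high-quality plus six reject categories
  (blurry, incomplete, fragment, clump, impurity, nucleus-only). Blur is
  measured as the Laplacian variance *inside* the object so background
  noise cannot mask it; multicellular clumps are caught mainly by the
  count of nucleus-coloured components. Only high-quality crops continue.
* **Segmentation** (`train_segmenter()`/`segment_cell()`): a per-pixel
  Gaussian colour classifier (linear discriminant on RGB) predicts the
  cell mask at 224 × 224, keeps the largest component, fills holes, and
  maps back to crop resolution; `remove_background()` sets outside-mask
  pixels to a uniform fill and is idempotent. `dice_bce_loss()` (binary
  cross-entropy plus one minus the soft Dice coefficient) is provided in
  closed-form-testable form. Crops with an empty mask are flagged and
  dropped, not propagated.
* **Size routing** (`route_by_size()`): the longer side of the mask's
  bounding box decides the channel — above 90 px large (254 × 254 crop),
  otherwise small (90 × 90), ties to small. The boundary value matches the
  two crop sizes; no other rule is implied by the application.
* **Classification** (`train_channel_classifier()`): per channel, a
  linear discriminant on morphometric features (nucleus-to-cell area
  ratio, contour irregularity `perimeter²/4πA`, chromatin texture, mean
  intensity, solidity, log area). The score is the logistic of the
  standardized discriminant projection — kept deliberately continuous,
  because a saturated probability (exact ties at 0/1 under class
  separation) makes specificity calibration degenerate. Training cells are
  passed through the *same* segmentation and background-removal path as
  pipeline cells, so the classifier is fitted on the feature distribution
  it will be scored on; fitting on ground-truth masks instead produces a
  distribution shift and false positives at inference.
* **Threshold calibration** (`calibrate_threshold()`): data are split
  7:2:1 (train/validation/test); the operating threshold is the smallest
  candidate achieving specificity ≥ 99.8% on the validation split, with
  calls at score ≥ threshold; if unattainable the threshold is placed
  above all scores with a warning. By construction the achieved
  calibration specificity is assertable exactly. The resulting operating
  sensitivities (roughly 0.7–0.8 on held-out synthetic cells) reflect the
  same stringency/sensitivity trade-off that motivates calibrating to
  specificity in the first place.
* **Slide scoring** (`run_slide()`): tile → detect → NMS → crop → QC →
  segment → route → classify → aggregate, with per-cell provenance (patch,
  box, confidence, QC category, channel, score, call) and monotone
  non-increasing stage counts. The ETC% denominator is QC-passed cells
  ("total cells" is ambiguous between pre- and post-QC objects; post-QC is
  used and the choice is configurable at the reporting layer).

## Diagnosis layer

`etc_fraction()`, `slide_call()` (boundary positive at the cutoff, so the
named 0.2% operating point is attainable), `confusion_metrics()`
(sensitivity/specificity/PPV/NPV in percent with exact Clopper–Pearson 95%
intervals by default, Wald optionally; printed percentages round half-up
to one decimal), `find_cutoff()` (candidates are midpoints of sorted
unique values; the default rule maximizes sensitivity subject to maximal
specificity, Youden optional, and reproduces maximal specificity on its
own discovery data by construction), `corrected_proportion()` (observed
proportion divided by detection sensitivity, capped at 100%), `roc_auc()`
(rank-sum AUC, identical to the trapezoidal area, with a Hanley–McNeil
Wald interval), and `compare_groups()` (thin delegation to Mann–Whitney,
paired Wilcoxon, and Pearson chi-square without continuity correction).
`cohort_report()` assembles model-vs-cytology tables, the percent increase
in positive findings, and stratified sensitivities. Proportion intervals
use an exact method because the reported single-cell intervals in this
setting are consistent with one; the AUC interval is Wald because that is
the stated convention for AUCs.

## The synthetic-data module

`simulate_cell_counts()` draws negative-binomial bin counts around
`depth × (copy/2) × g(GC)`, with a quadratic multiplicative GC bias
`g(gc) = 1 + b₁(gc−0.45) + b₂(gc−0.45)²` (defaults b = (1, −6)) — the
minimal shape producing curvature the lowess correction must remove. The
dispersion can be set directly or derived from a target MAPD: for
near-normal ratios `MAPD = 2σ/√π`, so the required ratio variance is
`(m√π/2)²` and the negative-binomial dispersion supplies what Poisson
noise at the given depth does not; a target below the Poisson floor fails
with the attainable minimum. Measured MAPD tracks the target within ±0.05
across 0.1–0.6 and is monotone. The synthetic GC landscape varies at a
scale of tens of bins — deliberately finer than copy-number events,
because a GC trend confounded with event-scale position lets the GC
correction absorb real signal.

`render_cell()` draws a cytoplasm blob with a Fourier-perturbed boundary
and an interior nucleus whose area fraction, contour irregularity and
chromatin texture are the controlled morphology parameters.
`sample_cell_spec()` draws these from class-conditional distributions
(benign: nucleus/cell ratio ≈ 0.28 ± 0.07, irregularity ≈ 0.06,
texture ≈ 0.05; malignant: ≈ 0.52 ± 0.10, 0.16, 0.14 at the default
`effect = 1`). The classes overlap by construction so classifiers cannot
be trivially perfect, but the means differ in the direction
cytomorphology expects. These effect sizes are free parameters of the
generator, not estimates from real slides — no morphometric statistics of
real ETCs are available to fit them. The `effect` parameter scales the
malignant-vs-benign mean separation: defaults define the study
conditions, while the end-to-end count-recovery benchmark renders its
slides at `effect = 1.5` to realize its stated strong-separation
condition. The QC model's high-quality training crops span effects
0.8–1.6 so that strongly atypical (dark, nucleus-dominated) tumor cells
are recognized as cells rather than rejected as debris.

`render_slide()` places an exact number of malignant cells
(`round(n × fraction/100)`) plus junk objects drawn from the six QC reject
categories at non-overlapping positions, and emits ground-truth boxes
(global, 0-based, half-open), run-length-encoded masks, and labels.
`simulate_cohort()` draws per-patient ETC fractions log-normally around
0.45% for cancer patients (straddling the 0.2% cutoff) and near zero for
controls with a 10% borderline rate, mirroring the fraction scale of the
clinical setting.

## Problem sizes and reproducibility

All randomness is funnelled through one seeded generator per call; no
global RNG state leaks. The test suite's standing choices: the shared
imaging fixture trains on 24 annotated patches, 30 crops per QC class,
40 segmentation crops and ~800 cells per channel; the breakpoint benchmark
runs 200 replicates on a 120-bin chromosome; clonal calling uses 20 clone
plus 20 normal cells over a 720-bin genome; the QC-cascade property uses
20 paired slides. These sizes were chosen as the smallest at which the
benchmarked quantities are stable, and they are stated here so the
reported numbers are interpretable.

## What the synthetic benchmarks do and do not show

Passing tests demonstrate that the implementation is internally correct
(oracle equivalences, closed-form losses, exact bookkeeping), that the
genomic arm recovers planted clonal structure under calibrated noise, and
that the imaging cascade's operating logic behaves as specified on
images whose class differences are real but synthetic. They do **not**
demonstrate clinical performance: rendered cells lack stain variability,
scanner artefacts, focal-plane variation and the full morphological
diversity of real cytology; the published AUCs and cohort results on
patient slides are properties of trained deep networks and patient data
that this package does not contain and does not claim to reproduce.
Detection of tumor-cell *clusters* is likewise out of scope — the
single-cell design assumes clustered specimens are triaged by a reader.

## Known limitations

* Slide-level specificity at desk scale is limited by the per-cell
  false-positive rate: on a 50-cell synthetic slide a single false call
  already exceeds the 0.2% cutoff, so demo cohorts use elevated planted
  fractions; the cutoff's regime is tens of thousands of cells per slide.
* The concordance criterion is a re-derivation (Pearson ≥ 0.8, single
  linkage, cluster size ≥ 2), not the original published rule.
* CBS p-values are permutation-based with early stopping; the smallest
  attainable p is 1/(nperm+1), so `alpha` below ~1e-4 requires raising
  `nperm`.
* The segmenter is a colour model: it would not separate touching cells
  of identical colour (those are handled as clumps by QC instead).
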