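---
title: "Quantification methods for comparative cardiac-injury studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for comparative cardiac-injury studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

`myoquant` re-implements, as tested R functions, the quantification stages
of a comparative myocardial-infarction study design: spiny mouse (*Acomys
cahirinus*) versus laboratory mouse (*Mus musculus*, C57BL/6) after
ligation of the left anterior descending coronary artery. Every stage can
be exercised on synthetic inputs with known ground truth, so the whole
pipeline is testable on a laptop without any imaging or sequencing data.
This vignette documents the models and conventions behind each stage, the
parameters that matter, and what the synthetic data do and do not emulate.

## ECG: QRS amplitude and duration

**Signal model of the generator.** A beat is a triplet of Gaussian
deflections — Q (negative), R (positive), S (negative) — centred at
`t_R - w/2`, `t_R`, `t_R + w/2` for a QRS width `w` (default 10 ms, a
murine scale). Beats are placed at a constant RR interval implied by the
heart rate, with centres snapped to the sample grid so the narrow
deflections are rendered at their nominal peak amplitudes. Optional
additive components are a 0.5 Hz sinusoidal baseline wander and white
Gaussian noise. When a signal-to-noise ratio is requested, `snr_db` is the
standard power ratio: the noise variance is the mean square of the
noiseless waveform divided by `10^(snr_db/10)`.

Ground truth (per-beat peak indices, amplitudes, onsets and offsets) is
computed **from the noiseless waveform with exactly the conventions of the
analysis stage** — baseline 0, wave edges where the waveform re-crosses
baseline ± 5% of that wave's peak amplitude. With Gaussian deflections the
tails of adjacent waves overlap slightly, so the rendered peak amplitude
differs from the nominal parameter in the fourth decimal; the recorded
truth is the rendered value.

**Baseline (the electrically neutral point).** The isoelectric reference
is the median of per-beat inter-QRS medians (middle half of each RR
interval), or the global median when beats are unknown. This estimator is
exactly translation-equivariant, which the tests exploit.

**R-peak detection.** The published study cites an external detection
algorithm without reproducing it; we implement a replaceable
Pan–Tompkins-style strategy adapted to narrow murine complexes: running-
median detrending (200 ms window), a short moving average (4 ms) acting as
a crude matched filter, squaring, then local maxima above an adaptive
threshold (30% of the median of the strongest candidates) separated by a
40 ms refractory period, each refined to the local maximum of the
detrended voltage. On the synthetic conditions used in the tests (1 kHz,
480 bpm, 60 s, 10 dB) sensitivity and precision are 1.0; no claim of
fidelity to the study's exact detector is made.

**Segmentation.** Q and S are the most negative extrema in 50 ms windows
before/after each R peak (sized for murine QRS widths); amplitudes are
signed and baseline-relative; durations are `(offset - onset)/fs`. Beats
whose windows cross the trace boundary are skipped with a warning.

## Echocardiography

`FS = (LVIDd - LVIDs)/LVIDd x 100` and `EF = (LVIDd^3 - LVIDs^3)/LVIDd^3 x
100`, computed from M-mode diameters **averaged over five replicates
first** — the order matters for heterogeneous replicates and the
parameter-average-first convention is the one implemented. The cubic EF
dominates FS for any `0 <= LVIDs <= LVIDd`. A systolic diameter exceeding
the diastolic one (possible in severe dyskinesia) yields negative values
and a quality flag rather than an error.

## Colour thresholding and the HSB convention

All colour gates use the ImageJ-style 0–255 integer HSB scale with
inclusive bounds; hue wraps around only when `hue_min > hue_max`, which no
published gate needs. Scar = H 140–200, S 10–255, B 0–255; whole tissue =
H 60–255; birefringence bins red 1–13, orange 14–25, yellow 26–52, green
53–110 (S 10–255, B 20–255), expressed relative to their sum (total
birefringence = 100%). Pixels with H = 0 or H > 110 fall outside all four
bins and are excluded from the total.

The synthetic section generator renders a tissue disk on a white
background with a wedge of prescribed area fraction carrying the scar (or,
in Evans-blue mode, the dye-excluded) hue. Hue jitter is clipped one hue
unit inside the gate so that 8-bit RGB round-trip quantization cannot move
a pixel across a gate boundary.

## Automatic histogram thresholds

Four published criteria are implemented on the 256-bin histogram and each
is verified in the test suite against an exhaustive 256-candidate
evaluation of its criterion:

* **Iterative intermeans / isodata** (the historical meaning of the
  "Default" method identifier): the Ridler–Calvard condition
  `t = (mu_below + mu_above)/2`, solved as the first crossing
  `t >= (mu0(t) + mu1(t))/2` — unique, unlike the fixed points of the
  naive iteration, which can be multiple.
* **Yen**: maximum-correlation criterion.
* **Triangle**: line from the histogram peak to the foot of the longer
  tail; the threshold maximizes the deviation of the histogram below that
  line. On bimodal histograms this criterion lands near the base of the
  dominant peak; on a mixture of N(50, 10) and N(200, 10) populations the
  threshold varies over roughly 75–180 across random draws while still
  misclassifying under 2% of pixels — a wider range than intuition
  suggests, and the tests assert the honest property (threshold strictly
  between the modes, misclassification < 2%) rather than a narrow window.
* **Moments** (Tsai): moment-preserving fractile; the threshold is the
  first grey level whose cumulative probability reaches `p0` (ties resolved
  toward the lower level so a symmetric two-level image separates). The
  test oracle re-derives `p0` by numeric root finding on the third-moment
  mismatch, independent of the closed-form quadratic.

Foreground polarity is explicit (`foreground = "bright"` or `"dark"`);
recipes state it where it matters (heart size thresholds the dark tissue
on a bright background).

## Background subtraction, filters, skeletons

Rolling-ball background subtraction is implemented as grayscale
morphological opening with a disc of the stated radius, subtracted and
clamped at zero. This matches the contract of the classic plugin —
constant backgrounds map to zero, features smaller than the ball are
preserved — without claiming bit-exact equality to any particular ball
shape. A consequence worth knowing: **large flat structures are
background by definition** and are removed; biologically that is right
(real staining is textured at the 50 px scale), and the synthetic
generator renders region-like channels (WGA, MLC-2v, isolectin, PDGFRb) as
dense speckle textures for the same reason.

The median filter uses a square window of side `2 * radius + 1`; despeckle
is the binary 3×3 median; the unsharp mask is
`(image - weight * blur)/(1 - weight)` with the blur's sigma as its
radius. Skeletons are Zhang–Suen thinned; a junction is a skeleton pixel
with ≥ 3 skeleton neighbours under 8-connectivity (adjacent junction
pixels merge into one junction), and branches are the connected components
of the skeleton after junction pixels are removed. Particle analysis is
8-connected with ImageJ-style "exclude on edges" and "include holes".

## Section morphometry

Scar fraction is scar-gate area over tissue-gate area per level, averaged
**unweighted** over the six levels of a stack (whether the study weighted
by tissue area is not derivable from its text; a weighted variant would be
a one-line change and the per-level table is returned). Evans-blue infarct
fraction is `1 - perfused/tissue` per level averaged over four levels,
with the dye gate exposed in configuration — a colour-gate replacement for
the study's manual tracing, chosen for reproducibility.

Heart size follows the published chain: green channel → Gaussian blur →
triangle threshold (dark foreground) → largest connected component off the
border, holes filled. The triangle threshold lands roughly 1.6–1.9 blur
sigmas from the dominant histogram peak, so the segmented boundary shifts
by about that much and the relative area error scales like `3.5 * sigma /
r`. The recipe's default sigma of 50 px is small relative to the ~10^4-px
hearts in full-resolution slide scans; on desk-scale fixtures the tests
use the same chain at matched geometry (a 1000 px-radius disk with sigma
4), where the analytic disk area is recovered within 2%.

Wall thickness is measured along five rays cast from the tissue centroid
at equally spaced angles across the scar's angular extent (the study
states only the count of measurement points; the ray construction is this
package's choice), thickness being the chord length of the tissue mask
along each ray.

## Fiber architecture

**Waviness** is arc length over the endpoint chord, `W >= 1`, exactly 1
for straight monotone paths and invariant under rigid motions and
scaling. Batch summaries take per-frame fiber means then a grand mean,
warning below the study's conventions (10 fibers/frame, 6 frames). The
generator draws fiber axes from an axial von Mises distribution and bends
each fiber sinusoidally with the amplitude solved (at the generator's own
vertex sampling) so the polyline's W equals the target exactly.

**Anisotropy** accumulates per-pixel intensity gradients over the ROI into
the normalized 2×2 structure tensor and scores `(l1 - l2)/(l1 + l2)`; the
reported orientation is the fiber axis (perpendicular to the dominant
gradient) in `[0, 180)`. Gradients use Scharr kernels — a central
difference cross-smoothed with (3, 10, 3)/16 — because the plain central
difference has an anisotropic frequency response that biases the
orientation of period-8 textures by more than 1 degree, while Scharr keeps
it within ~0.15 degrees. The score is gain- and offset-invariant by
construction. Whether the study's plugin reports this eigenvalue ratio or
a related tensor-difference score is not derivable from its text; the
eigenvalue form is implemented.

**Box-counting dimension and lacunarity.** Box sizes default to powers of
2 from 2 px to 45% of the shorter side. Grids are scanned at the tight
origin plus four slipped origins (fixed 1–4 px shifts, toroidal so no
spurious partial boxes appear at the raster boundary). `D` is the
least-squares slope of `log N(eps)` against `log(1/eps)` where `N(eps)` is
by default the **minimal count over grid positions** — the tightest cover,
which is the definition of the box-counting dimension. Averaging per-scan
slopes instead (selectable via `aggregate = "mean_scan"`) systematically
underestimates `D` on self-similar patterns because shifted grids
over-cover them at coarse scales (Sierpinski depth 7: 1.53 versus the
analytic 1.585, which min-cover reproduces exactly). Lacunarity is the
mean over scans and sizes of `(sigma/mu)^2 + 1` of occupied-box masses.
The conventional minimum-pixel-density setting of 0.40 used by fractal
box-counting tools is ambiguous; it is interpreted here as a per-scan
filter flagging grid scans
whose sampled foreground density falls below 0.40 of the mean scan
density, configurable and off by default, with flags always reported.

The preprocessing chain for fractal analysis is fixed in the published
order — rolling ball 75 → unsharp (2 px, 0.60) → median 1 → intermeans
threshold (bright) → despeckle — and pinned by a regression test. Note
that the median filter commutes with thresholding (a monotone-function
identity), so some permutations of the tail of the chain provably cannot
change the mask; the order-sensitivity tests therefore target the
operators that genuinely do not commute.

## Cell-counting recipes

All recipes compose the primitives above with the published parameters:
nuclei = rolling ball 50 → median 1 → threshold (intermeans for Hoechst,
Yen for EdU) → particles (exclude edges, include holes); scar ROI = WGA
channel with median radius 20 and Yen; dividing cardiomyocytes = MLC-2v
segment minus the capillary segment (isolectin: rolling ball 5, median 20,
intermeans), counting nuclei whose centroid lies in the remainder and
scoring positives by ≥ 1 px overlap with the marker mask but none with
isolectin; arteries = alpha-SMA components measured by maximum Feret
diameter (max pairwise hull distance plus one pixel extent), retained iff
≥ 10 µm and centred in the WGA ROI, with density per scar mm²; coverage =
rolling ball 50 → Moments threshold → positive area over ROI area. The
nucleus–marker association rule (component overlap ≥ 1 px) and the Feret
reading of "largest diameter" are this package's choices where the study
describes manual steps.

The generator places non-overlapping nuclei by rejection sampling (an
explicit error when the density is infeasible), renders capillaries as a
contiguous textured band — capillary beds are spatially coherent, and the
median-radius-20 recipe requires that coherence — and renders all
region-like channels full-width so the large median window is not eroded
at frame edges. In noiseless mode every recipe recovers the generator
truth exactly, which the acceptance tests assert as identities.

## Maturation transcriptomics

All multivariate steps work on `log2(x + 1)` of the FPKM-scale matrix; the
study does not state its transform, and this choice is applied
consistently to the variance filter, PCA, and Pearson correlations.
Variable genes: variance > 0.5 and expression > 1 FPKM in more than two
samples (i.e. at least three). PCA is computed on the gene-centred matrix;
per component the gene loadings (eigenvector × singular value, normalized
to unit maximum absolute value so the 0.2 threshold is applied on a
comparable scale) are thresholded at |loading| > 0.2 and capped at the 50
largest per component, ties broken by gene ID; the union over the first
five components is returned. With five components the cap bounds the union
at 250 genes; the study's own count of 300 is arithmetically inconsistent
with its stated caps, and the implementation enforces the caps and reports
actual counts.

The sample network connects samples whose Pearson correlation over the
selected genes exceeds the threshold; 0.6 (the Methods value) is the
default, with the figure-caption variant 0.4 equally available — the
conflict is surfaced, not resolved. Zero-variance samples are isolated
with a warning. Layouts use seeded Fruchterman–Reingold. The cumulative
category score is the per-sample sum of per-gene z-scores across samples
(the study names no formula; raw-sum and mean-expression variants would be
trivial substitutions and the z-sum is documented as the default
definition); constant genes have no defined z-score and are dropped with a
warning. Maturation ratios are Tnni3/Tnni1 and Myl2/Myl7 per sample,
linear and log2, NA-flagged when a denominator is non-positive.

**Synthetic expression model.** Per-gene lognormal baselines
(`meanlog 5, sdlog 1` in the study-condition fixture), negative-binomial
sampling (dispersion 0.02), a species-discriminant block of 60 genes at
±4 log2 (alternating signs — a one-signed block would leave cross-species
correlations high because baselines are shared, and mixed-sign blocks are
what real species signatures look like), and a 30-gene sarcomere set up 2
log2 in adult *Mus* and 0.3 in adult *Acomys*, emulating the attenuated
maturation of the spiny mouse. Four groups (species × age) of four
samples. Under these conditions the variance filter retains essentially
the planted genes, PC selection recovers them (Jaccard ≥ 0.95 over seeds),
and the thresholded network splits the samples by species in ≥ 90% of
seeds.

## What the synthetic data do not emulate

The generators give closed-form or constructed truth, not realism: ECG
beats are regular (no heart-rate variability, arrhythmia, or P/T waves);
sections are flat-hue wedges with no staining texture, section tears or
registration error; fibers are independent sinusoids, not entangled
bundles; nuclei are disks of one size with no clumping or out-of-focus
light; expression has no batch effects, library-size variation or
count-depth relation. Passing tests therefore demonstrate algorithmic
correctness against the stated conventions, not robustness to every
artefact of real acquisitions. Statistical testing across animal cohorts
(mixed ANOVA and post-hoc procedures) is deliberately out of scope; the
package stops at descriptive quantification.

## Problem sizes

The test and acceptance workloads are sized for a single CPU: 60 s ECG
traces at 1 kHz over five seeds; 400² px sections; 512² px fiber fields
and masks (Sierpinski depth 7 at 128²); one 2100² px disk for heart size;
1000-gene × 16-sample expression matrices over 10–20 seeds. The full
suite runs in a few minutes.
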