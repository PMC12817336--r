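---
title: "Models and methods behind ptcrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ptcrescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcrescue)
```

`ptcrescue` quantifies premature-termination-codon (PTC) readthrough rescue
from four assay families — dual-reporter flow cytometry, stop-codon-context
sequence analysis, two-channel proximity imaging, and calibrated enzymatic
activity with blot densitometry — and ships synthetic-data generators with
known ground truth for each. This vignette describes the underlying models,
the parameters that matter, and the numerical and design choices, so that a
reader can judge what a passing test suite does and does not demonstrate.

## The readthrough statistic

A dual reporter places a stop codon and its surrounding context between an
RFP and a GFP coding region. RFP reports how much reporter a cell
expresses; GFP is produced only when the ribosome reads through the stop.
Readthrough (TR) is quantified as

$$\mathrm{TR\%} \;=\; 100 \cdot
\frac{(\mathrm{GFP}/\mathrm{RFP})_\text{sample}}
     {(\mathrm{GFP}/\mathrm{RFP})_\text{control}},$$

where the control expresses an RFP-GFP fusion with no intervening stop and
therefore defines 100%. Before the ratio, events pass two gates: a scatter
window (FSC 23,000–75,000, SSC 12,500–67,500, inclusive, selecting intact
cells) and a fluorescence inclusion rule (RFP > 900 **or** GFP > 100,
strict, removing untransfected cells that carry only autofluorescence).
Both rule sets are raw linear instrument values and are exposed in
`gating_config()`.

Two estimator choices exist because "ratio of GFP to RFP signal" is
ambiguous at the population level:

- `ratio-of-means` (default): `mean(GFP)/mean(RFP)` over included events.
  This is stable when per-cell GFP approaches zero, which is the typical
  uninduced regime (readthrough fractions of 10^-4^–10^-2^).
- `median-of-ratios`: the median per-cell GFP/RFP. More robust to a
  minority of aberrant events, but noisier at near-zero GFP, where
  per-cell ratios are dominated by baseline fluctuation.

Self-normalization is exact by construction: `tr_statistic(x, x)` returns
100 for any nonempty gated table, which the tests assert.

Optional background correction subtracts the per-channel medians of an
untransfected well before forming ratios (flooring at zero). It is **off**
by default: the printed inclusion rule is the only unambiguous part of the
published procedure, and the correction changes estimates only when
baseline GFP is comparable to the readthrough signal.

### The generative model for flow samples

No generative model is published for this assay, so `reporter_cell_model()`
adopts the simplest one that reproduces the qualitative structure of a
transient-transfection experiment:

- a two-component scatter mixture: intact cells with Gaussian FSC/SSC, and
  a dim debris cloud at one fifth of the cell scatter, which falls outside
  the scatter gate with high probability;
- lognormal reporter expression $E$ among transfected cells
  (default meanlog `log(1e4)`, sdlog 0.8 — a bright, decade-wide
  transient-expression distribution on the raw instrument scale);
- channel signals $\mathrm{RFP} = g_R E + a_R$ and
  $\mathrm{GFP} = \theta\, g_G E + a_G$ with additive autofluorescence and
  multiplicative mean-one Gaussian measurement noise (CV 0.1);
- untransfected cells carry autofluorescence only.

$\theta$ is the true readthrough fraction; $\theta = 1$ encodes the fusion
control. Under this model the gated ratio-of-means estimator has
expectation $\approx (\theta\, g_G \bar E + a_G)/(g_G \bar E + a_G)$
relative to the control, so its bias is governed by the ratio of baseline
GFP to readthrough signal. The default baseline (`autofluor_gfp_mean` =
0.1 AU against a mean readthrough signal of 2.75 AU at $\theta = 2\times
10^{-4}$) keeps the relative bias below ~5% even for the weakest published
context; the printed estimates themselves imply that baseline GFP among
gated, transfected cells was negligible in the original assay. A larger
baseline would require enabling the background correction.

Preset $\theta$ values encode the study conditions: 0.002 (uninduced
p.Q82X context, ≈0.2%), 0.0002 (p.W188X, ≈0.02%), 0.0034 (p.Q427X,
≈0.34%), 0.005 (500 ng/µl G418, ≈0.5%), 0.01 (G418 + 1 nM CC-885, ≈1%) and
0.011–0.012 (G418 + 5 nM CC-885, above 1%).

### FCS3.0 profile

Files are written as FCS3.0 with one dataset: HEADER with segment offsets,
TEXT with `$DATATYPE` F or I, both byte orders, 32-bit parameters, and a
DATA segment in list mode. The reader honours exactly this profile. DATA
offsets wider than the 8-character header fields fall back to
`$BEGINDATA`/`$ENDDATA`, per the standard. Values round-trip bit-exactly at
float32 precision (`as_float32()` reproduces the quantization in memory).

## Stop-codon-context analysis

Coordinates are 1-based cDNA positions within the CDS (codon $k$ spans
$3k-2..3k$), the storage alphabet is DNA, and RNA input is normalized on
entry. The 23-nt SCC is ten nucleotides on each side of the stop; flanks
truncated by the CDS ends are padded with `-` and flagged. Stop-codon
leakiness is ranked UGA (1, most readthrough-prone) > UAG (2) > UAA (3),
and contexts are scored by Hamming distance of the stop-plus-4-downstream
window to the high-readthrough motif UGA CUAG. Near-cognate amino-acid
candidates are Trp/Cys/Arg at UGA and Gln/Tyr/Lys at UAG/UAA; a test
verifies by brute force over the standard genetic code that every candidate
decodes via a codon within one mismatch of the stop.

Truncation sizes are estimates only. Two conventions are exposed
(`precursor` counts every codon before the stop; `mature` subtracts the
signal peptide — 27 residues for the α-L-fucosidase precursor) and two mass
methods (count × mean residue mass, default 110 Da; or the sum of average
residue masses of the encoded sequence plus water). Published expected
masses for truncated variants do not always match a single convention —
glycosylation (≈2–3 kDa on the mature enzyme) and tags are not modeled —
so the operation exposes the conventions rather than asserting one.

The packaged `synthetic_fuca1_cds()` is a deterministic synthetic stand-in
with the precursor's length (466 codons + stop) and the three clinically
relevant codons planted (CAG at 82, TGG at 188, CAA at 427), so that
`c.244C>T`, `c.564G>A` and `c.1279C>T` create UAG/UGA/UAA stops at codons
82/188/427. It is not the RefSeq mRNA, and SCC *sequences* extracted from
it are synthetic; only the variant arithmetic is meaningful.

Reporter-oligo adapter trimming (`trim_reporter_oligo()`) is configurable
(default: leading `GTCACC`, one trailing base) because the vector-junction
definition is a cloning-design property, not derivable from the oligo
sequence itself.

## The imaging chain

`segment_channel()` reproduces a standard local-threshold segmentation
chain for small fluorescent objects, in order:

1. **Percentile contrast normalization** (`normalize_contrast()`): the
   0.35th and 99.65th intensity percentiles map to 0 and 1 (saturation
   0.35%, the common automatic-display default). Monotone and invariant to
   affine intensity transforms.
2. **Rolling-ball background subtraction**
   (`rolling_ball_background()`, radius 50 px): implemented as grayscale
   opening with a disc structuring element — the classical morphological
   form of the rolling-ball estimate; exactness versus a paraboloid ball is
   not claimed. The opening is computed in-package (disc decomposed into
   line segments with logarithmic sliding minima), since the available
   image library provides binary morphology only.
3. **Phansalkar local threshold** (`phansalkar_threshold()`, radius 15 px):
   foreground iff $v > m\,(1 + p e^{-q m} + k(s/r - 1))$ with local mean
   $m$ and standard deviation $s$ over the disc neighborhood; $k = 0.25$,
   $r = 0.5$, $p = 2$, $q = 10$ are the published formulation's defaults
   (only the radius is prescribed by the original analysis). Local
   statistics use replicate boundary handling.
4. **Adaptive filter** (`adaptive_filter()`, radius 1 px): the named
   plugin's behavior is not specified; a radius-1 median filter is the
   documented stand-in. On binary masks this is an exact majority vote
   over the plus-shaped neighborhood and removes isolated speckle.
5. **Erosion-marker watershed** (`watershed_split()`, 5 cycles): markers
   are components surviving five 3×3 erosions; a component that erodes
   away entirely keeps its pre-erosion extent as one marker (no object is
   lost); labels are assigned by geodesic propagation of markers across
   the mask, equivalent to a marker-constrained watershed of the distance
   transform for these convex objects.
6. **Measurement** (`label_objects()`): centroids, areas, boundary pixels,
   intensities; objects under `min_area_px` (default 2) are dropped and
   counted.

Distances (`nearest_distances()`) are object-based: for each source object
the centroid distance to the nearest target and the minimum
boundary-pixel distance to the nearest target, in µm. Overlapping objects
have edge distance 0; there are no negative depths. Equidistant targets
resolve to the lowest label, deterministically. Edge distances are exact:
candidates are pruned with the bound
$\text{center} - r_\max(\text{src}) - r_\max(\text{tgt})$ and boundary
pairs evaluated until no candidate can improve, which the tests check
against an unpruned $O(n^2)$ scan. Per-cell marker quantification
(`intensity_per_cell()`) normalizes integrated intensity by 2D mask area —
an explicit stand-in for cell volume in a single plane.

Analysis is 2D throughout (single confocal plane); 3D stacks are out of
scope.

### The scene generator and its calibration

`image_scene_spec()` describes a single-plane, two-channel scene: a target
channel of lysosome-like discs (diameters 0.22–0.26 µm by default, well
under the ~0.7 µm upper bound typical of these organelles) and a source
channel of enzyme puncta (0.2–0.22 µm) on a 0.1 µm/px grid. The source
puncta follow a two-component distance mixture with weight
`fraction_within_02um`:

- **lysosome-associated** (within 0.2 µm edge-to-edge): either a single
  punctum concentric with its lysosome (center-to-center near 0 — the
  luminal enzyme read against the membrane marker) or, when the associated
  pool exceeds the lysosome count, pairs of membrane-apposed puncta on
  roughly opposite sides of one organelle (edge distance 0.04–0.10 µm);
- **distal**: edge distances uniform in 0.27–0.34 µm.

Ground truth (centers, radii, and analytic nearest distances) is returned
alongside the rendered images; a test recomputes all distances from the
stored geometry and requires exact agreement.

Several geometric choices are calibrated against the measurement process
rather than chosen freely, because the acceptance-style recovery runs the
*full* chain on the rendered pixels:

- The local threshold necessarily includes part of the blur halo, so masks
  are slightly dilated and measured edge distances shrink by ≈0.05 µm
  (measured empirically on controlled disc pairs; centroid distances are
  unbiased). The distal band starts at 0.27 µm so that, after this shrink,
  distal puncta remain safely beyond the 0.2 µm classification radius.
- Two puncta merge into one mask below ≈0.5 µm center separation
  (measured); the generator enforces this separation between all puncta,
  and the lysosome spacing is derived from it so that punctum clusters of
  neighboring organelles can never collide. Opposite-side pairs are the
  only way two sub-resolution associated signals per organelle remain
  individually countable.
- The PSF default (σ = 0.5 px, FWHM ≈ 120 nm) is sharper than a
  diffraction-limited confocal. This is a deliberate generator
  idealization: at the prescribed 0.1 µm pixel size, a realistic PSF makes
  sub-300 nm objects inseparable, and the proximity statistics under test
  are about object geometry, not optics.
- The field is 160×160 px (a 16 µm single-cell crop). Percentile contrast
  normalization needs the bright-signal pixel fraction to exceed the 0.35%
  saturation tail; sparser fields would stretch background noise across
  the display range and flood the local threshold.
- The associated/distal composition is exact (`round(fraction × n)`) with
  randomized placement, rather than binomial, because the two-per-lysosome
  capacity makes the binomial upper tail physically unplaceable.

With the wild-type preset (fraction 0.6; 33 lysosomes, 90 puncta), the
expected pooled statistics through the full chain are ≈60% within 0.2 µm
and a mean center-to-center distance of ≈0.35 µm, consistent with a
luminal enzyme in organelles of this size. What the recovery tests show is
that the chain measures the planted geometry faithfully; they do not show
that real micrographs look like these scenes — real images have
out-of-focus light, clustered and partially overlapping organelles,
heterogeneous brightness, and a wider PSF, all of which this generator
deliberately omits.

## Activity calibration and densitometry

The 4-MU standard curve is an ordinary least-squares line of fluorescence
on nmol with a **free intercept** — the blank is the 0-nmol standard, which
the curve is required to include. A non-positive fitted slope is a
calibration error. Back-calculated 4-MU below the blank floors at zero
with an explicit flag rather than propagating negative amounts.

Specific activity uses the bookkeeping

$$\text{activity [mU/mg]} = \frac{\text{nmol}_{4\text{-MU}} \times
\text{dilution}}{\text{incubation [min]} \times \text{protein [mg]}},$$

with 1 mU = 1 nmol/min. `protein_mg` is the protein mass in the reaction
before dilution; reaction-volume terms cancel in this formulation, which
is defined here unambiguously because published volume bookkeeping is only
partially stated. The forward simulator uses the same formula, so a
noise-free round trip is the exact identity (asserted to 10^-10^).

Densitometry starts from band-intensity tables, never raw blot images.
`normalized_band_ratio()` computes loading-control-normalized levels
relative to a baseline condition (e.g. release-factor levels relative to
untreated), and is invariant to any global intensity gain.
`readthrough_efficacy_from_blot()` anchors full-length variant bands on a
wild-type reference lane loaded at a known fraction of the variant load:
with a 1:100-load reference, a variant band equal to the reference band
means 1% efficacy. The load fraction is a parameter (`0.01` default)
because diluted-reference designs also use 10% loads. Activity presets
encode the published recovery levels (1.46 and 0.88 mU/mg for the two
rescuable variants under G418 alone; 3.65% and 1.19% of untreated
wild-type under dual treatment, against a wild-type preset of 200 mU/mg —
the midpoint of the reported 100–300 mU/mg range).

Viability is absorbance normalized to the untreated-control mean, × 100.

## Reproducibility and problem sizes

Every generator takes a `seed` and restores the caller's RNG state;
identical spec + seed gives bit-identical output, which the pipeline
runner (`run_pipeline()`) extends to whole runs (byte-identical FCS files
and reports). The test suite and the acceptance script size their
simulations for tight feedback: readthrough recovery uses 10 samples of
10^5^–2×10^5^ events per condition (enough that the Monte-Carlo error of
the mean estimate is well below the estimator's bias budget), calibration
round trips are deterministic, and proximity recovery pools ~900 puncta
across 10 scenes per condition.

## Known limitations

- The flow model has no spectral spillover, no doublets, and no
  time-dependent drift; the gates are the printed raw-scale rules and are
  not re-derived from the data.
- SCC analysis does not predict readthrough efficiency from sequence (the
  mechanisms are not modeled), and NMD sensitivity is out of scope.
- The imaging chain is 2D, assumes sub-micrometer convex objects, and its
  published plugin steps (adaptive filter, adaptive watershed) are
  approximated by documented stand-ins.
- Densitometry assumes the band table is already background-corrected and
  within the film/detector linear range.
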