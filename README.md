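# ptcrescue

Quantification tools for premature-termination-codon (PTC) readthrough
rescue experiments, built around the assays used to study nonsense variants
of the lysosomal enzyme α-L-fucosidase (FUCA1) in fucosidosis:

- **Dual-reporter flow cytometry.** An RFP–(stop/SCC)–GFP construct reports
  translational readthrough (TR): RFP measures expression, GFP is produced
  only when the ribosome reads through the stop codon. After scatter gating
  (FSC 23,000–75,000; SSC 12,500–67,500) and a fluorescence inclusion rule
  (RFP > 900 or GFP > 100), TR is the GFP/RFP signal ratio normalized to a
  stop-free RFP-GFP fusion control:
  `TR% = 100 · (GFP/RFP)_sample / (GFP/RFP)_control`.
  The package reads and writes FCS3.0 files directly.
- **Stop-codon-context (SCC) sequence analysis.** HGVS-like coding
  substitutions (`c.244C>T`) are applied to a CDS, classified, and the
  23-nucleotide SCC extracted; stop codons are ranked by leakiness
  (UGA > UAG > UAA), scored against the high-readthrough motif UGA CUAG,
  and annotated with near-cognate amino-acid candidates and the predicted
  truncated-protein size.
- **Two-channel proximity imaging.** The segmentation chain used for
  lysosomal colocalization-by-distance: percentile contrast normalization,
  rolling-ball background subtraction (radius 50 px), Phansalkar local
  thresholding (radius 15 px), radius-1 adaptive median filtering,
  erosion-marker watershed (5 cycles), and object-based nearest-neighbor
  center-to-center / edge-to-edge distances with within-0.2 µm fractions.
- **Enzymatic activity and densitometry.** 4-methylumbelliferone (4-MU)
  standard-curve calibration to specific activity in mU/mg
  (1 mU = 1 nmol/min), percent-of-wild-type summaries,
  loading-control-normalized band ratios, readthrough efficacy from
  diluted-reference blot designs, and viability normalization.
- **Synthetic-data generators** for every assay, with known ground truth
  (true readthrough fraction θ, true activity, true object geometry), so
  each analysis stage is testable end to end without instrument data.
  Named presets encode the study conditions.

Everything is data-frame-first: event tables, object tables, plate and band
tables come in and go out as tibbles, and fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate an untreated p.Q82X reporter sample and a 100% fusion control,
gate, and quantify readthrough:

```r
library(ptcrescue)

control <- gate_events(simulate_flow_sample(flow_preset("fusion-control"),
                                            n_events = 50000, seed = 1))
sample  <- gate_events(simulate_flow_sample(flow_preset("q82x-untreated"),
                                            n_events = 100000, seed = 2))
tr_statistic(sample, control)
#> <tr_result> TR = 0.2008% (ratio-of-means)
#>   sample ratio 0.002002 / control ratio 0.9966; 56657 events included
```

The preset's true readthrough fraction is θ = 0.002, and the gated
estimator recovers it as ≈ 0.2% of the fusion control — the uninduced
readthrough level of the p.Q82X stop-codon context.

Sequence-level reasoning for the three clinical nonsense variants:

```r
variant_report(synthetic_fuca1_cds(),
               c("c.244C>T", "c.564G>A", "c.1279C>T"))[, 1:8]
#> # A tibble: 3 × 8
#>   variant   position ref   alt   codon_index class    stop_codon scc_23nt
#>   <chr>        <int> <chr> <chr>       <int> <chr>    <chr>      <chr>
#> 1 c.244C>T       244 C     T              82 nonsense UAG        AGTGACCTATTAGC…
#> 2 c.564G>A       564 G     A             188 nonsense UGA        CCCACGTCTGTGAC…
#> 3 c.1279C>T     1279 C     T             427 nonsense UAA        GGCAAAAGTATAAG…
```

Calibrated enzyme activity from a simulated noise-free assay plate:

```r
plate <- simulate_activity_plate(activity_preset("q82x-g418-max"), seed = 1)
curve <- fit_standard_curve(plate)
specific_activity(plate, curve)
#> # A tibble: 1 × 4
#>   sample_id     nmol_4mu activity_mU_per_mg floored
#>   <chr>            <dbl>              <dbl> <lgl>
#> 1 q82x-g418-max    0.219               1.46 FALSE
```

Proximity analysis of a synthetic two-channel lysosome scene:

```r
scene <- simulate_image_scene(proximity_preset("wild-type"), seed = 1)
report <- run_proximity(scene)
attr(report, "pooled")
#> # A tibble: 1 × 4
#>   fraction_within mean_center_um n_objects n_scenes
#>             <dbl>          <dbl>     <int>    <int>
#> 1             0.6          0.363        90        1
```

About 60% of enzyme puncta lie within 0.2 µm of a lysosome and the mean
center-to-center distance is ≈ 0.36 µm — the lumen-versus-membrane
organization the wild-type preset encodes.

## Package layout

- `R/simulate-flow.R`, `R/fcs.R`, `R/gating.R`, `R/tr.R` — cytometry:
  generator, FCS3.0 I/O, gates, TR statistic, plate runner.
- `R/sequence.R` — CDS handling and stop-codon-context analysis.
- `R/simulate-image.R`, `R/imaging.R`, `R/proximity.R` — scene generator,
  segmentation chain, distance analysis.
- `R/simulate-assay.R`, `R/quantify.R` — activity/blot generators and
  calibration, densitometry and viability operations.
- `R/presets.R`, `R/pipeline.R` — the study-condition preset catalog
  (`inst/extdata/presets.yaml`) and the seeded end-to-end pipeline runner.
- `vignettes/ptcrescue-methods.Rmd` — models, assumptions and numerical
  choices.
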