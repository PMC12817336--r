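# Named study-condition presets. Each preset records the ground-truth
# parameter the synthetic generators reproduce, so downstream estimates are
# recovery tests against a known truth.
flow:
  base_model:
    transfected_fraction: 0.6
    expression_log_mean: 9.2103403719762
    expression_log_sd: 0.8
    rfp_gain: 1.0
    gfp_gain: 1.0
    autofluor_rfp_mean: 30.0
    autofluor_gfp_mean: 0.1
    autofluor_sd: 0.3
    fsc_mean: 49000.0
    fsc_sd: 8000.0
    ssc_mean: 40000.0
    ssc_sd: 9000.0
    debris_fraction: 0.05
    noise_cv: 0.1
  presets:
    fusion-control:
      theta: 1.0
      note: "RFP-GFP fusion without a separating stop codon; defines 100% readthrough"
    q82x-untreated:
      theta: 0.002
      note: "p.Q82X (UAG) stop-codon context, no treatment; ~0.2% readthrough"
    w188x-untreated:
      theta: 0.0002
      note: "p.W188X (UGA) stop-codon context, no treatment; ~0.02% readthrough"
    q427x-untreated:
      theta: 0.0034
      note: "p.Q427X (UAA) stop-codon context, no treatment; ~0.34% readthrough"
    g418-500:
      theta: 0.005
      note: "500 ng/ul G418 alone; ~0.5% readthrough (p.Q82X and p.W188X contexts)"
    g418-cc885-1nM:
      theta: 0.01
      note: "G418 plus 1 nM CC-885 release-factor degrader; ~1% readthrough"
    q82x-g418-cc885-5nM:
      theta: 0.012
      note: "p.Q82X context, G418 plus 5 nM CC-885; above 1% readthrough"
    w188x-g418-cc885-5nM:
      theta: 0.011
      note: "p.W188X context, G418 plus 5 nM CC-885; above 1% readthrough"
untransfected:
  transfected_fraction: 0.0
  note: "untransfected cells measured as plate control"
activity:
  defaults:
    protein_mg: 0.05
    dilution_factor: 10
    incubation_min: 30
  presets:
    wt-untreated:
      true_activity_mU_per_mg: 200.0
      dilution_factor: 100
      note: "wild-type enzyme, untreated lysate (reported range ~100-300 mU/mg)"
    q82x-untreated:
      true_activity_mU_per_mg: 0.0
      note: "p.Q82X untreated; activity undetectable"
    w188x-untreated:
      true_activity_mU_per_mg: 0.0
      note: "p.W188X untreated; activity undetectable"
    q82x-g418-max:
      true_activity_mU_per_mg: 1.46
      note: "p.Q82X, maximal G418-only recovery"
    w188x-g418-max:
      true_activity_mU_per_mg: 0.88
      note: "p.W188X, maximal G418-only recovery"
    q82x-g418-cc885-5nM:
      true_activity_mU_per_mg: 7.3
      note: "p.Q82X, 100 ng/ul G418 + 5 nM CC-885; 3.65% of untreated wild type"
    w188x-g418-cc885-5nM:
      true_activity_mU_per_mg: 2.38
      note: "p.W188X, 100 ng/ul G418 + 5 nM CC-885; 1.19% of untreated wild type"
proximity:
  presets:
    wild-type:
      fraction_within_02um: 0.6
      n_lamp1: 33
      n_fuca1: 90
      note: "wild-type lysosomal pattern: ~60% of enzyme puncta within 0.2 um of a lysosome, mean center-to-center ~0.35 um"
blot:
  presets:
    erf3a-cc885-5nM:
      target_abundance: 0.5
      note: "release factor eRF3a degraded to 50% of untreated at 5 nM CC-885"
    efficacy-dual:
      target_abundance: 0.03
      wt_reference_load_fraction: 0.01
      note: "full-length variant at 3% of wild type under dual treatment, 1:100-load reference design"
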