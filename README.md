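# scoliquant

Quantitative analyses for glycinergic models of adolescent idiopathic
scoliosis (AIS): a tested R implementation of the measurement and
statistics pipeline used to link glycine transporter 1 (GLYT1/SLC6A9)
dysfunction to spinal curvature, from zebrafish spinal-cord calcium
imaging down to cohort genetics.

It is written for researchers who need to run — or audit — these
analyses on their own data or on simulated data:

* **Bilateral spinal calcium activity** (`neural_activity`):
  ΔF = F(t) − F0 extraction with manual or rolling-percentile
  baselines, robust event detection, the left–right **alternation
  index** — (number of consecutive event pairs on opposite sides of
  the spinal cord) / (total events − 1) — side-specific event
  frequency (Hz), relative intensity (% of mean ΔF), and total signal
  (time-integral of ΔF).
* **Body-curvature morphometrics** (`morphometrics`): the scalar
  **θ angle** from midline coordinates (vertex at maximal chord
  deviation; θ = 180° − vertex interior angle), the curved phenotype
  call (θ ≥ 10°, boundary inclusive), penetrance, dose–response
  summaries, and t/ANOVA group comparisons.
* **Surface EMG** (`semg`): zero-phase 15–1000 Hz band-pass,
  zero-mean, reference-guided ECG template subtraction, bending
  (reference-contraction) normalization, and descriptive burst
  metrics.
* **Cohort statistics** (`cohort_stats`): variant allele/case
  frequencies, two-sided Fisher exact association on 2×2 allele
  tables with cross-product odds ratios, plasma-glycine group
  comparisons.
* **Glycine uptake assays** (`uptake_assay`): rates in
  nmol/min/mg protein, percent of wild type, membrane-protein-level
  normalization, ANOVA with per-variant contrasts against WT.
* **Gene-set enrichment** (`enrichment`): hypergeometric
  over-representation with GeneRatio (overlap / mapped query genes)
  and Benjamini–Hochberg adjustment, over user-supplied GMT sets.
* **Synthetic data** (`synthetic_data`): seeded generators for every
  input above — antiphase-coupled bilateral event trains rendered as
  calcium traces, circular-arc midlines of known θ, binomial cohort
  tables, four-channel sEMG with injected ECG, uptake plates — so the
  whole pipeline runs and is tested without any external download.

## Worked example

Simulate one minute of bilateral spinal calcium activity at 10
frames/s with a 0.9 side-switching probability, then quantify it:

```r
library(scoliquant)

sim <- simulate_bilateral_traces(
  cpg_sim_params(event_rate = 0.2, switch_prob = 0.9,
                 duration = 60, noise_sd = 0.3, seed = 42))
s <- activity_summary(sim$traces)
cat("events detected:", s$n_events, "\n")
cat("alternation index:", round(s$alternation_index, 3), "\n")
cat("left-side frequency (Hz):", round(s$left_frequency_hz, 3), "\n")
cat("ground-truth index:", round(alternation_index(sim$events), 3), "\n")
#> events detected: 15
#> alternation index: 0.857
#> left-side frequency (Hz): 0.1
#> ground-truth index: 0.867
```

The detector recovers 15 events and an alternation index of 0.857
against a ground truth of 0.867 — a strongly alternating, healthy-like
pattern (an index near 1 means strict left–right alternation; values
near 0.5 are what uncoordinated, side-independent activity gives).

Morphometrics and cohort statistics follow the same style:

```r
theta_angle(simulate_midline(midline_sim_params(theta_deg = 23)))
#> [1] 22.98  # degrees, recovered from the arc's coordinates

allele_frequency(15, 1696)   # variant alleles in the AIS cohort
#> [1] 0.884  # percent (printed to 3 significant figures)

association_test(cohort_table("AIS", 15, 1696),
                 cohort_table("controls", 7, 6438))
#> Fisher p = 2.2e-06, odds ratio = 8.2
```

The allele frequency of 0.884% in cases versus 0.109% in controls
differs with a Fisher exact p of order 10⁻⁶: rare heterozygous
variants are strongly enriched in the AIS cohort.

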