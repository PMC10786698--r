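---
title: "Methods and design of scoliquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of scoliquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoliquant)
```

scoliquant implements the quantitative chain of a glycinergic model
of adolescent idiopathic scoliosis: spinal central pattern generators
(CPGs) produce left–right alternating motor output; impaired
glycinergic inhibition (GLYT1/SLC6A9 loss of function) disrupts that
alternation; the imbalance propagates to paraspinal muscle activity
and, ultimately, axial curvature. Each link has its own measurement —
calcium-imaging alternation, sEMG, curvature morphometrics, cohort
genetics, transporter-function assays — and this vignette documents
the models, parameter choices and numerical decisions behind each.

## Bilateral calcium activity

**Model.** Per-ROI fluorescence is treated as
`F(t) = F0(t) + sum of event transients + noise`. ΔF is defined as
`F(t) − F0`. F0 is either user-supplied (`baseline_manual()`) or
estimated as the 10th percentile of F over a centered 20 s rolling
window (`baseline_rolling_percentile()`). The percentile baseline is
the package's default because the original measurements used a
manually selected baseline, which is not reproducible; a low rolling
percentile tracks the between-event floor and absorbs slow drift.
Its two costs are documented and tested: (i) ΔF keeps a small
positive offset (≈ `-qnorm(p)·sd` of the noise), which the detector
removes by median-centering, and (ii) under a linear drift of slope
`a` the baseline is biased by about `a·window·(0.5 − p)`, so strong
drift inflates recovered amplitudes (the amplitude-recovery test uses
a drift of 0.05 units/s, where the bias stays inside 5%).

**Event detection.** The published analysis identified "patterned
events" manually; scoliquant substitutes a deterministic detector so
results are reproducible:

1. noise SD is estimated robustly as `mad(diff(ΔF))/sqrt(2)` —
   differencing whitens the slow transients, so the estimate is not
   inflated by the events themselves;
2. ΔF is median-centered and thresholded at `threshold_k` (default 3)
   robust SDs, with hysteresis: an excursion is a run above half the
   threshold that lasts at least 2 samples and reaches the full
   threshold at least once (single-sample excursions cannot be real
   transients at any realistic time constant);
3. within an excursion, local maxima must also have topographic
   prominence above the threshold — this rejects noise re-crossings
   on a transient's slow decay while keeping genuine consecutive
   same-side events;
4. a refractory rule (`min_interval_s`, default 0.5 s) keeps the
   larger of two events whose onsets are closer than the interval;
5. left and right events with onsets within `coincidence_window_s`
   (default 0.2 s) merge into one `bilateral` event. Synchronous
   bilateral activation is the discoordination phenotype, so these
   pairs count as *not* alternating.

Onsets are reported at the upward threshold crossing and are accurate
to about two frames at 10 fps; with a 3-SD threshold an occasional
noise excursion is expected (about one per few minutes per side), and
two same-side events closer than roughly one second with amplitudes
near threshold may merge — the detector's temporal resolution limit.

**Statistics.** The alternation index is the number of consecutive
event pairs on opposite sides divided by (total events − 1); it is 1
exactly when sides strictly alternate with no bilateral events, and
its expectation under side-independent activity is 0.5. Side-specific
frequency is the event count over the recording duration (the
published quantification uses the left side). "Total signal" is
operationalized as the trapezoidal time-integral of ΔF per ROI, since
no formula was published. The index is computed by default on the
per-side *summed* ΔF across ROIs (matching quantification of total
left- and right-side activity); matched ROI pairs can be analyzed by
passing single-ROI trace sets.

## The synthetic CPG generator

`simulate_bilateral_traces()` generates ground-truth event trains and
renders them into traces:

* **Timing** is a refractory renewal process: inter-event gaps are
  `min_gap` (default 0.75 s) plus an exponential tail, with mean gap
  `1/event_rate`. A CPG is quasi-rhythmic, not memoryless; a strictly
  Poisson train would produce coincident left/right events that no
  healthy CPG produces. `min_gap = 0` recovers the Poisson case.
* **Laterality** is a Bernoulli switching process: each event lands
  on the side opposite its predecessor with probability
  `switch_prob`, so the expected alternation index of the ground
  truth *equals* `switch_prob` — an analytic recovery target for the
  whole pipeline.
* **Shape** is the unit-peak double-exponential kernel
  `exp(-t/tau_decay) − exp(-t/tau_rise)` (defaults 0.8 s / 0.1 s),
  with gamma-distributed amplitudes (`amplitude_mean`,
  `amplitude_cv`), a linear baseline, and i.i.d. Gaussian noise. The
  kernel's closed-form area `(tau_decay − tau_rise)/peak` is the
  oracle for the total-signal integral.

The generator emulates the *statistical* structure the analysis
assumes — event sparsity, antiphase coupling, transient shape, drift
and noise. It does not emulate shared-noise correlations between
ROIs, photobleaching curves, motion artifacts, or amplitude
adaptation; passing tests therefore validate the estimators under the
stated model, not robustness to every imaging pathology. No
event-rate or amplitude statistics were published for the original
recordings, so the defaults (0.2 events/s, amplitudes 10 units over
0.3–0.5 units of noise) are chosen for testability, not fidelity.

Recovery performance under these conditions (tested): with events at
10× noise all ground-truth events are re-detected; at 5× noise and
well-separated events recall exceeds 95%; the full
simulate → ΔF → detect → index pipeline recovers `switch_prob` within
±0.05 (mean over 10 fish, 240 s recordings each at 10 fps — sizes
chosen so the suite stays quick while the binomial error on the index
is a few percent).

## Curvature morphometrics

θ is computed from ordered midline coordinates: the vertex is the
point of maximal perpendicular distance from the head–tail chord, and
θ = 180° minus the interior angle at the vertex between the
vertex→head and vertex→tail vectors. This construction was chosen
because the original figure defines θ only pictorially; it returns 0
for a straight body, is invariant under rotation, translation,
reflection, uniform scaling and point-order reversal, and on a
circular arc of central angle 2θ it returns exactly θ
(inscribed-angle geometry) — which is why `simulate_midline()` builds
arcs: the oracle is closed-form. A 3-point moving average (endpoints
pinned) stabilizes vertex selection under pixel noise; on noise-free
51-point arcs it perturbs θ by well under 0.1°.

The curved phenotype is θ ≥ 10° with the boundary *included*, and
penetrance is `100·n_curved/n_total`, returned unrounded — the
published display rounds to roughly three significant figures
(11.9%, 13.4%, 12.5%), and one published figure (1.769%) keeps four,
so rounding is left to formatting rather than baked into the value.
`dose_response()` adds a nondecreasing-penetrance flag as the
qualitative dose-dependence check. Group comparisons use the unpaired
Student's t test (two groups) or one-way ANOVA (more), the tests
quoted in the original figure legends.

## Surface EMG

Preprocessing follows the acquisition chain: zero-phase 4th-order
Butterworth band-pass at 15–1000 Hz, then per-channel mean
subtraction. At the 2000 Hz sampling rate the nominal 1000 Hz upper
edge sits at Nyquist, so it is clipped to `0.45·fs` — the filter
family, order and clip are package choices (only the band itself was
specified). Reapplication is a near no-op on muscle-band signals;
broadband noise reaching the band edges loses about 1% RMS of
transition-band energy per extra pass.

ECG removal is reference-guided template subtraction: beats are
detected on the reference channel (recorded high on the trunk, where
cardiac pickup dominates) as peaks of its 5–40 Hz envelope with a
0.35 s refractory; the signal channel is averaged across beat windows
(−60 ms, +80 ms) into a template, the template is low-passed at
150 Hz (QRS energy is band-limited, so this strips template-estimation
noise without touching beat morphology), and a least-squares-scaled
copy is subtracted at each beat. With fewer than three usable beats
the signal is returned unchanged with a warning — the conservative
failure mode. On synthetic recordings with a known injected ECG this
removes > 95% of the template energy and leaves template-free signals
essentially untouched.

Bending normalization divides each standing channel by the RMS of the
same channel in the same-side trunk-bending recording; the published
methods state only that bending recordings "were used as
normalization", so per-side RMS division is a declared convention.
Burst metrics (windowed RMS, burst = window above `burst_k`× the
median window RMS) are explicitly exploratory descriptors of the
irregular-burst vs stationary distinction; no equivalence to the
original qualitative reading is claimed.

## Cohort statistics

The association between variant alleles and case status is tested
with the two-sided Fisher exact test on the 2×2 allele table — the
standard choice for rare variants; the original report does not name
its test, so the printed p-value (2.39×10⁻⁶) is treated as an
order-of-magnitude consistency check, and indeed the Fisher p on the
printed counts (15/1,696 vs 7/6,438) is 2.2×10⁻⁶. The odds ratio is
the sample cross-product, with the Haldane–Anscombe 0.5 correction
applied (and flagged) only when a cell is zero. The allele table is
exposed in the result so any alternative convention (carriers rather
than alleles, chi-square rather than Fisher) can be re-run. Plasma
glycine is compared carrier vs control with the unpaired t test,
optionally within one age stratum (the published comparison is within
adolescents).

## Uptake assays

Rates are `nmol / (min · mg protein)`; an optional helper converts
scintillation counts via the specific activity (`2.22e6` dpm/µCi,
with a declared counting efficiency). Percent-of-WT divides each
genotype's mean rate by the WT mean; membrane normalization divides
percent-of-WT by the relative membrane protein level (WT = 1), making
the published "no significant differences after membrane
normalization" claim arithmetic: a variant with 40% uptake and 0.4
relative membrane level normalizes to exactly 100%. Group comparison
is one-way ANOVA followed by per-variant contrasts against WT on the
pooled residual variance (Dunnett-style comparison to control); since
only "one-way ANOVA" was specified, the multiplicity adjustment is
configurable (`p.adjust` methods, default Holm) and recorded in the
output.

## Enrichment

`enrich()` is a generic hypergeometric over-representation engine:
for a universe of N genes, a set covering K of them and n query genes
mapped to at least one set, the p-value is the upper tail
P(X ≥ k) of the hypergeometric distribution at the observed overlap
k, with Benjamini–Hochberg adjustment across sets. GeneRatio is
`k/n`, the published definition; unmapped query genes are reported
but excluded from n. The default universe is the union of all
annotation-set members — the common default of enrichment tools when
no background is supplied — and can be overridden, since the original
background was unstated. No ontology ships with the package:
annotation sets arrive as GMT files, so results depend on the user's
annotation release by design.

## Numerical and testing conventions

* All generators draw every random quantity from one explicit seed
  per call; equal seeds give bit-identical outputs.
* Degenerate inputs (empty traces, zero margins, zero WT rate, zero
  bending RMS, fewer than two events) raise classed parameter errors
  rather than returning NaN.
* Exact tests are verified against brute-force enumeration (all 2×2
  tables with fixed margins; all hypergeometric overlap outcomes) on
  small instances, and simulation-based tests (type-I error, power,
  binomial penetrance recovery) run at sizes where the binomial
  standard error makes the tolerance meaningful (600–1000
  replicates).
* Percentages are returned unrounded everywhere; display rounding is
  the caller's concern.

## Known limitations

The detector's temporal resolution (~1 s for same-side events near
threshold) and the percentile baseline's drift bias are described
above. The sEMG burst metrics are descriptive only. The enrichment
engine deliberately excludes SNP→gene mapping and ontology handling.
Human-subject analyses (radiographic Cobb angles, clinical
recruitment) and raw-image processing (ROI segmentation, midline
extraction from photographs, blot densitometry) are out of scope:
inputs begin at per-ROI traces, midline coordinates and count tables.
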