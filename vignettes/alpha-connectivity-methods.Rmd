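---
title: "Methods: alpha-band dbWPLI connectivity, Network-Based Statistics, and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-band dbWPLI connectivity, Network-Based Statistics, and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaconn)
```

This vignette is the package's own account of its methods: the analysis
chain and its assumptions, the generative model behind the synthetic
cohorts, the tunable parameters and why their defaults are what they are,
the numerical conventions, and the limits of what the simulations can
establish about real infant EEG.

## The analysis chain

The pipeline reproduces the standard sensor-space connectivity workflow
for infant cohort designs:

1. **Validity segmentation.** Manual annotations mark spans where the
   infant was inattentive, interference occurred, or artefacts were
   present. `valid_segments()` merges these (union of intervals; overlaps
   are normalised, never an error) and complements them within
   `[0, duration)`. Intervals are half-open and sample indexing is 0-based
   throughout, so a sample at time `t = i / fs` belongs to an interval iff
   `start <= t < end`.
2. **Epoching.** `epoch_segments()` slides a 1-s window in 0.5-s steps
   (50% overlap) within each valid segment; a segment of length `L` yields
   `floor((L - 1) / 0.5) + 1` epochs and no epoch crosses a segment
   boundary. `amplitude_artefact_filter()` then drops epochs whose peak
   absolute amplitude exceeds 200 µV on any channel — a conventional
   automatic bound for infant scalp EEG, exposed as a parameter because
   labs differ. Subjects enter the analysis only with **strictly more
   than** `min_epochs = 120` clean epochs pooled across stimulus
   conditions; 120 exactly is excluded.
3. **Spectra.** Each epoch is demeaned per channel (a DC-leakage guard
   that can be disabled), Hanning-tapered and Fourier transformed. With
   1-s epochs the resolution is 1 Hz and bin *k* sits at *k* Hz. A pure
   8 Hz sine concentrates ~2/3 of its power in the 8 Hz bin and >99% in
   the 7–9 Hz main lobe: the Hann window trades leakage width for side
   lobe suppression, and the 0.25/0.5/0.25 amplitude split across the
   main lobe is the price.
4. **Connectivity.** `dbwpli()` computes, per frequency bin and channel
   pair, the debiased weighted phase lag index from the imaginary parts of
   the per-epoch cross-spectra, then averages bins across the band
   (default 7–8 Hz, i.e. bins {7, 8}), per-entry and missing-aware.
5. **Statistics.** `nbs_test()` for network-level group differences;
   `choose_test()` / `mann_whitney()` for scalar summaries;
   `correlation_analysis()` for brain–behaviour associations.

## The dbWPLI estimator

With per-epoch cross-spectra $X_j = F_a(j)\,\overline{F_b(j)}$, the
estimator is

$$
\widehat{\mathrm{dbWPLI}}
  = \frac{\sum_{j \ne k} \Im(X_j)\,\Im(X_k)}
         {\sum_{j \ne k} |\Im(X_j)|\,|\Im(X_k)|}
  = \frac{\big(\sum_j \Im X_j\big)^2 - \sum_j (\Im X_j)^2}
         {\big(\sum_j |\Im X_j|\big)^2 - \sum_j (\Im X_j)^2}.
$$

The pairwise-product form over *distinct* epochs removes the positive
bias of the squared weighted PLI: under independence each product has
expectation zero, so the estimator's expectation is approximately zero
rather than positive, and slightly negative values are legitimate. The
right-hand identity is what the implementation evaluates (three running
sums per pair per bin); the test suite checks it against the literal
$O(n_{\text{epochs}}^2)$ double sum at tolerance $10^{-10}$ on random
complex tensors. Properties the suite verifies: symmetry, boundedness by
1, near-zero grand mean over independent noise (|mean| < 0.01 at 32
channels × 1000 epochs), and insensitivity to purely real (zero-lag)
cross-spectra.

Numerical conventions:

* **Undefined entries.** The denominator is zero iff at most one epoch
  has a non-zero imaginary cross-spectrum (e.g. exactly zero-lag mixing
  with no noise). Such entries are `NA` and are excluded from band
  averages, `global_dbwpli()` and `masked_mean()`; a summary is `NA` only
  if *every* contributing entry is. Exactly-zero imaginary parts have
  measure zero in real data, so this convention only matters for
  synthetic edge cases. Because $|\text{numerator}| \le$ denominator
  algebraically, near-cancellation cannot push the ratio outside
  $[-1, 1]$.
* **FFT normalisation** is irrelevant to dbWPLI (any per-epoch scale
  cancels); power spectra use $|F|^2/N$.
* **Overlapping epochs** are treated as independent observations in the
  estimator, as is conventional in this literature. The 50% overlap makes
  neighbouring epochs positively dependent, which inflates the effective
  sample size the estimator assumes; the simulations quantify the
  variance consequence implicitly (all calibration checks use the same
  overlap).
* **Band averaging order**: per-bin dbWPLI first, then the average across
  bins — not dbWPLI of averaged cross-spectra.

## Network-Based Statistics

`nbs_test()` is the Mann–Whitney flavour of NBS: per edge, the pooled
subject values are ranked once; the group-A rank sum gives U and a
tie-corrected normal-approximation Z with no continuity correction
(all-tied edges get Z = 0, a conservative choice that avoids 0/0). Edges
with Z above the threshold (default 1.96; one-tailed with group A
hypothesised larger — the direction of the over-connectivity hypothesis
in this study design; `two.sided` thresholds |Z|) form a graph whose
connected components are scored by **extent** (edge count, the default)
or **intensity** (sum of supra-threshold Z). Group labels are permuted
(default 5000 draws; exhaustive enumeration with a warning when the
label space is smaller) and each observed component is scored against
the null of the per-permutation *maximum* component statistic with the
add-one estimator $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$,
which never returns 0. Ranks and tie-corrected variances are invariant
under relabelling, so they are computed once and each permutation only
re-sums ranks — this is what makes the calibration simulations cheap.

**Calibration.** The permutation test is exact for a continuous
component statistic. Extent, however, is small-integer-valued at desk
scale (16 channels, 10+10 subjects): the null of the maximum extent has
only a few atoms, the achievable significance level just below 0.05 can
be substantially smaller, and the realised family-wise error rate falls
*below* nominal. The acceptance suite therefore checks the intensity
statistic against the two-sided binomial interval around 0.05 (600 null
cohorts) and checks extent against the upper bound only — conservative,
never anti-conservative. Power is checked with extent: a 5-edge path
shifted by 3 within-group SDs in one group must be recovered (≥4 of 5
planted edges inside a significant component) in ≥90% of runs.

## The synthetic generator

No public data accompany this study design, so the generator defines the
conditions under which everything is tested.

* **Background noise** is $1/f^{\alpha}$ with $\alpha = 1$ by default
  (EEG-like; $\alpha = 0$ gives white noise for unit tests), synthesised
  by spectral shaping of white noise and normalised to unit SD per
  channel.
* **Volume conduction** is emulated by a zero-lag mixing matrix: shared
  $1/f$ sources added instantaneously to several channels. This creates
  strong real cross-spectra and no imaginary part — the failure mode
  dbWPLI is designed to ignore, and the suite verifies it does.
* **Phase-lagged coupling** is a shared oscillator observed by both
  channels of a pair: channel *i* gets $\sin(2\pi f t + \theta(t) +
  \eta_i(t))$ and channel *j* the same with an added fixed lag (default
  $\pi/2$, the most visible lag for an imaginary-part metric). The
  shared phase $\theta$ drifts as a Brownian path (1 rad/√s) so distinct
  epochs sample fresh absolute phases. The per-channel jitter $\eta$ is a
  stationary Ornstein–Uhlenbeck process with relaxation time 0.5 s —
  chosen so consecutive 1-s epochs decorrelate — and stationary SD
  `jitter_scale * (1 - strength)`. A mean-reverting process is essential
  here: a Brownian jitter would accumulate without bound and destroy
  phase locking for *every* strength < 1 on long recordings, leaving no
  usable strength dial. With the default `jitter_scale = 2` rad,
  strength 0 gives effectively uniform relative phases. The resulting
  empirical strength→dbWPLI map at ~200 epochs is approximately
  {0, 0.07, 0.5, 0.99, 1} for strengths {0, 0.25, 0.5, 0.75, 1}:
  monotone (the property the tests rely on) but deliberately not linear —
  the field's literature prescribes no generative model for this, so the
  mapping is a package design choice, documented rather than attributed.
* **SNR** is the oscillator-to-noise amplitude ratio per coupled channel
  (default 1, i.e. oscillator SD equals noise SD; `Inf` switches noise
  off for analytic checks).
* **Cohorts.** Each subject draws a true coupling strength from its
  group's Normal distribution truncated to [0, 1]; each trait scale is
  `intercept + slope * strength + N(0, noise_sd)` (defaults 2, 6, 1.5 —
  an ADI-R-RRB-like range of roughly 2–8 over the strength range with
  noise comparable to the signal span). Trait scores stay real-valued by
  default so a noiseless trait is an *exact* monotone map of strength;
  `round_traits = TRUE` gives integer, zero-clipped ADI-R-like scores at
  the cost of ties. Sex (Bernoulli, default 0.5 male) and age
  (≈ N(470, 45) days, the usual 14-month window) are decorative
  demographics for table layouts.

**Default scale.** The simulated montage defaults to desk scale (8–32
channels in the tests and acceptance runs; channel count is always a
parameter, never hard-coded) as a stand-in for the ~116-channel
high-density montages of real studies. Problem sizes used by the suite —
16-channel networks with 10+10 subjects and 500 permutations for NBS
calibration, 600 null repetitions, 16-subject cohorts at 250 Hz with
70-s recordings for the end-to-end run — were chosen as the smallest
sizes at which the checked properties are statistically decidable.

## Cohort statistics conventions

* **Test dispatch**: t-test only if Shapiro–Wilk passes in *both* groups
  and Levene passes (all at α = 0.05); otherwise two-sided Mann–Whitney.
  A zero-variance group forces Mann–Whitney with a warning (Shapiro–Wilk
  is undefined on constants).
* **Exact vs asymptotic U p-values**: exact by full enumeration of the U
  null when there are no ties and $n_1 n_2 \le 400$; otherwise the
  tie-corrected normal approximation, never with continuity correction
  (this reproduces published z values, e.g.
  $z = (104 - 130)/\sqrt{20 \cdot 13 \cdot 34 / 12} = -0.958$ for U = 104
  with groups of 20 and 13; `mann_whitney_z()` computes this directly
  from a printed U).
  The exact two-tailed p doubles the smaller tail; without ties the U
  null is symmetric, so this equals summing outcomes as or more extreme
  in both tails. With ties an "exact" request falls back to asymptotic
  with a warning.
* **Effect size** r = z/√N, the convention under which published r
  values (e.g. −0.17 for z = −0.958, N = 33) reproduce.
* **Winsorizing**: every occurrence of the maximum moves to the largest
  strictly smaller value; an all-equal vector is unchanged. Note the
  operation is *not* idempotent in general — repeated application keeps
  shrinking the range — so it is applied exactly once, as a sensitivity
  analysis for a single extreme subject.
* **FDR scope**: Benjamini–Hochberg is applied only to the scales not
  declared a priori; pre-registered hypotheses are reported uncorrected,
  mirroring common practice in replication designs.
* **ADI-R RRB subtypes** are sums of configured "ever" item scores. The
  shipped default item sets (`adi_r_subtype_items()`) are a
  literature-informed convention — published factor solutions differ —
  and are meant to be replaced by each study's own configuration; a
  missing item makes that subject's subtype score missing without
  affecting other subtypes.

## Degenerate inputs and tie-breaks

* Annotations may overlap or abut: unioned before complementing.
* `fs * epoch_length` (and the step) must be whole numbers of samples;
  anything else is an error, not a silent rounding.
* An all-tied edge in NBS scores Z = 0; an undefined (NA) connectivity
  entry causes that edge to be dropped from NBS with a warning.
* `supra_components()` uses strict `>` thresholding.
* Empty edge masks are an error; an edge mask never contains self-edges.
* Permutation p-values are never 0 by construction.

## What passing tests do and do not show

The generator produces stationary, narrow-band, single-lag couplings in
Gaussian-ish noise with clean annotations. Real infant EEG has
non-stationary oscillations, broadband artefacts (EMG, blinks, motion)
that survive amplitude thresholds, imperfect manual validity coding,
reference-electrode effects, and genuinely unknown coupling structure.
Passing this suite shows the *machinery* is correct and calibrated —
the estimator matches its definition, the permutation test controls
family-wise error, the pipeline recovers planted effects — not that any
particular scientific finding in real data is right. Likewise the
selected-connection mask is a required input: the fronto-central edge
set from the prior cohort is not published as coordinates, so analyses
of real data must supply their own mask (the tests use synthetic
masks over planted edges).

## Known limitations

* Sensor space only; no source localisation or leakage correction
  beyond the phase-lag metric itself.
* No ICA, channel interpolation or artefact waveform modelling; the
  amplitude threshold is the only automatic rejection implemented.
* EDF input is not supported; recordings are delimited matrices with a
  JSON sidecar (`read_recording()` / `write_recording()`).
* The strength→dbWPLI mapping is empirical and generator-specific;
  simulated effect sizes do not translate to physiological ones.
* Covariate-adjusted analyses (ANOVA/GLM over age, sex, behaviour,
  power) are out of scope; the per-epoch condition labels recorded in
  the provenance table are the hook for such analyses.
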