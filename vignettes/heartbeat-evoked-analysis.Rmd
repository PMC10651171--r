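---
title: "Heartbeat-evoked responses under the local-global paradigm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat-evoked responses under the local-global paradigm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herclust)
```

## The scientific problem

Patients with disorders of consciousness are classified at the bedside into a
minimally conscious state (MCS) or an unresponsive wakefulness syndrome
(UWS), a distinction with a high misdiagnosis rate when based on behaviour
alone. The local-global auditory paradigm probes residual cognition with two
embedded levels of regularity: each trial is five 50-ms tones at a 150-ms
onset asynchrony, and the 5th tone defines the trial as standard or deviant
both *locally* (within the trial: is the 5th tone equal to the first four?)
and *globally* (across the block: is the trial the frequent ~80% type or the
rare ~20% type?). XX blocks use five equal tones as the frequent stimulus;
XY blocks use four equal tones plus a different 5th.

`herclust` analyses two neural signatures in this design:

* **ERPs** — EEG averaged on the 5th-sound onset (epochs up to 1000 ms), and
* **HERs** (heartbeat-evoked responses) — EEG averaged on the first R-peak of
  the cardiac cycle following each 5th sound (epochs up to 500 ms), the
  neural response to the heartbeat itself in the context set by the
  preceding stimulus.

The **local effect** is the pooled mean over local-deviant epochs
(LDGS + LDGD) minus local standards (LSGS + LSGD); the **global effect** is
global deviants (LSGD + LDGD) minus global standards (LSGS + LDGS). Group
differences (MCS vs UWS) in these channels-by-time contrast maps are tested
with a non-parametric spatiotemporal cluster-permutation test, and the
per-subject means over significant cluster points ("combined clustered
effects") feed within-group median tests, between-effect correlations, and a
cross-validated linear discriminant classification.

Because the underlying patient recordings are restricted data, the package
ships a first-class synthetic-cohort generator, and all statistical
machinery is verified on simulated cohorts with known ground truth.

## The statistical core

### Pointwise statistic and clusters

For each (channel, time) point, group maps are compared with an unpaired
Wilcoxon rank-sum Z (normal approximation, midrank ties, no continuity
correction; positive Z means the MCS-like group tends larger). The
preliminary mask is all points with two-sided pointwise p below 0.05, split
by the sign of Z. Within each time sample, masked channels are grouped into
spatially connected components under the sensor neighbourhood graph (two
sensors are neighbours at Euclidean distance at most 4 cm, boundary
inclusive); components with fewer than four distinct channels are dropped;
surviving same-sign components at adjacent time samples are merged when they
share at least one channel, transitively.

### Monte Carlo correction

Each cluster's statistic is its maximum |Z|. The permutation null reassigns
the group labels (sizes preserved): for each of 10,000 random partitions
(exhaustive enumeration when the number of distinct partitions is smaller),
the partition statistic is the maximum |Z| over that partition's own
suprathreshold mask, zero when the mask is empty. The Monte Carlo p of a
cluster is the proportion of partition statistics at least as large as the
cluster's, ties counting as exceedances, reported as a plain proportion.
The min-channel and wrapping rules are not re-applied within permutations
(only the max-|Z| matters for the null; a configuration flag enables full
per-permutation clustering for sensitivity analyses). This max-statistic
reading is the only one that yields a proper exceedance null for the
"proportion of partitions with a more extreme outcome" logic.

### Surrogate-heartbeat control

A significant HER effect could in principle be stimulus activity leaking
into heartbeat-locked epochs. The specificity control reallocates each
heartbeat timing uniformly at random over the recording (peak count
preserved, collisions redrawn, no minimum separation — the epoch rejection
rules handle implausible pairs), rebuilds the HER epochs and contrast maps,
and re-runs the group cluster test per surrogate (100 surrogates by default,
at a reduced partition count of 1,000). A surrogate counts as exceeding the
observed clustered effect when its best same-sign cluster matches or exceeds
it in **both** combined-effect magnitude and channel extent; the surrogate p
is the exceedance proportion. Three design choices deserve note:

* the conjunction compares *combined-effect magnitudes* (the group
  difference of the per-subject cluster means) rather than the rank-based
  cluster statistic. Surrogate cohorts lose the majority of their epochs to
  the 500-ms interbeat rule, so their maps are intrinsically noisier;
  rank-based statistics of the observed data then beat surrogates for purely
  mechanical reasons, while effect magnitudes scale with map noise and keep
  the comparison fair;
* cluster size is measured in distinct channels — the unit in which cluster
  sizes are expressed throughout the analysis (the minimum-cluster rule is
  also a channel count); member-point counts are dominated by temporal
  fragmentation, which again differs mechanically between observed and
  surrogate maps;
* the control targets the strongest *significant* observed cluster — only
  effects the analysis actually reports are submitted to the control. When
  nothing is significant the control returns NA ("nothing heartbeat-locked
  to test"), which summaries treat as maximally non-significant.

### Cohort statistics and classification

Within-group tests of whether combined clustered effects have non-zero
median use the Wilcoxon signed-rank Z (zeros dropped, midranks; a pure sign
test is available), Bonferroni-corrected at alpha = 0.05/8 for the 2 groups
x 2 signals x 2 levels family. Between-effect associations use Spearman
correlations with the t approximation. Classification uses a linear
discriminant with pooled within-class covariance and equal priors (the
cohort's diagnostic base rates are not population rates) in stratified
fivefold cross-validation, over all four feature triads and the full quad
with shared fold assignments; a trace-scaled ridge (1e-6) backs up singular
covariances.

## Preprocessing chain

1. **Band-pass 1–25 Hz**: zero-phase (forward-backward) Butterworth of order
   4, with reflection padding so filter transients fall outside the data. A
   Hamming-windowed FIR mode is available: the two standard readings of a
   "Butterworth band-pass with Hamming windowing" are internally
   inconsistent (Hamming windows define FIR designs), so the Butterworth
   order is taken as the quantitative anchor and both modes satisfy the same
   passband properties.
2. **Iterative channel rejection**: per channel, the trapezoidal area under
   the absolute signal is z-scored across channels; channels above 3 SD are
   removed and the procedure repeats until stable (cap 10 iterations). A
   zero-variance spread across channels rejects nothing.
3. **ICA-ECG recovery**: the cardiac field artifact is isolated by a
   symmetric FastICA (logcosh contrast, deterministically seeded
   initialisation, unmixing estimated on an evenly spaced 10,000-sample
   subset). The cardiac component is chosen by a kurtosis gate (excess
   kurtosis at least 6 — QRS trains are sparse spike trains; no passing
   component raises an error advising an external ECG) followed by the
   combined rank of heart-period rhythmicity (share of the power-envelope
   autocorrelation energy at 0.6–1.5 s lags) and kurtosis. The component's
   source time course is the ICA-ECG; the EEG is reconstructed without it.
4. **Low-correlation interpolation**: per channel, Pearson correlations with
   graph neighbours are averaged with inverse-distance weights
   (inverse-square available); channels below 0.80 are replaced by
   spherical-spline interpolation (order 4, regularisation 1e-5, 20 Legendre
   terms) of their remaining neighbours. Isolated channels are never
   interpolated; more than half the montage failing the rule is treated as a
   degenerate recording.
5. **Common average reference** over retained channels, then an optional
   channel-subset selection (e.g. a 64-channel analysis montage, supplied by
   configuration since no canonical subset list exists).

R-peaks are detected on the ICA-ECG by a sliding-window local-maximum rule
(window 600 ms, refractory 300 ms, adaptive amplitude floor at 0.4 of the
95th percentile of window-maximum amplitudes; polarity resolved by running
both orientations). Ectopic interbeat intervals are flagged where the
absolute first difference of the interval series has a peak exceeding 3
robust SDs; the robust scale is the MAD of the interval series itself, which
(unlike the MAD of the difference series) stays calibrated when a sizeable
fraction of the differences are ectopic. Flagged intervals stay in the
record but their bounding beats never serve as HER lock points. Interactive
peak editing is replaced by a deterministic corrections table.

### Epoch rejection rules

Candidate HER epochs (first R-peak strictly after each 5th sound, window
[0, 500) ms; stimulus epochs [0, 1000) ms, half-open in samples, 0-based
locks) are rejected with one primary reason each, evaluated in the fixed
order STIM20MS (5th sound within 20 ms of the nearest R-peak, either
direction), IBI500 (adjacent interbeat interval under 500 ms), ECTOPIC,
AMP300 (absolute amplitude over 300 uV on any channel), EDGE (window
overruns the recording). No baseline correction is applied to either epoch
type: HER baselines are contaminated by the preceding stimulus, and a
correction is not part of the analysis the package reproduces (a flag
exists). A latency-balance control verifies with rank-sum tests that the
mean 5th-sound-to-lock latency does not differ between groups in any of the
four pooled condition categories.

## The synthetic cohort generator

`simConfig()` fixes the study conditions; `simulateSubject()` /
`simulateCohort()` generate recordings with ground-truth sidecars. The
defaults are the paradigm's own values: 250 Hz, 64 channels (hemispherical
cap of radius 9 cm; a planar grid is available), five 50-ms tones at 150-ms
SOA, intertrial interval uniform on 1350–1650 ms, 20% rare trials, patients
with 2 XX + 2 XY blocks of 90 trials (about 200 s per block), controls with
1 + 1 blocks, cohort sizes 46/40/11. Tone onsets are tracked in continuous
milliseconds and quantised per sound, so the 5th tone is exactly 600 ms
after the 1st even though 150 ms is 37.5 samples at 250 Hz.

The EEG model is: background noise + cardiac field artifact + planted
effects. Choices that matter:

* **Background noise** is a low-rank spatially smooth field (16 latent AR(1)
  sources with coefficient 0.9, spread by 5 neighbour-averaging passes,
  95% of variance) plus white channel-specific sensor noise, total SD 10 uV.
  The smoothing targets neighbour-channel correlations around 0.85–0.9, as
  in band-limited volume-conducted scalp EEG; this realism is load-bearing
  twice: the 80% weighted-correlation interpolation rule only behaves as on
  real data when clean channels correlate highly, and candidate clusters
  under the null only form at realistic rates when maps are spatially
  smooth (with independent channels the min-4-channel rule makes the
  dataset-level false-positive rate collapse to ~0 instead of ~alpha).
* **Cardiac artifact**: a fixed 80-ms biphasic QRS-like template placed at
  R-peaks drawn with truncated-normal interbeat intervals (mean 800 ms, SD
  60 ms, truncation at +/-3 SD and a 250-ms floor), mixed across channels
  by a spatially smooth (dipolar-like) topography with a 60 uV peak at the
  strongest channel. The amplitude is chosen so the artifact is prominent
  enough for ICA to recover the ECG reliably — the regime the original
  pipeline demonstrably operated in (R-peaks from ICA-ECG match a real ECG
  within 0–4 ms); at much lower gains the artifact is information-
  theoretically irrecoverable from the mixture.
* **Planted effects**: deviant-minus-standard increments (half-sine bumps
  evaluated at sample midpoints, so even a 3-sample window carries
  amplitude) on a spatially contiguous 8-channel set near the montage
  centre, in the canonical windows — ERP local 236–328 ms, ERP global
  800–850 ms post 5th sound; HER local 400–412 ms, HER global 112–130 ms
  post R-peak. Default amplitude 5 uV = half the noise SD (per-epoch SNR
  0.5). Group semantics mirror the observed pattern: MCS-like (and control)
  subjects carry full local and global effects; UWS-like subjects carry
  attenuated local effects with signal-specific signs (+0.4 for ERP,
  −0.4 for HER, matching the reported positive UWS ERP-local and negative
  UWS HER-local effects) and null global effects. MCS-like subjects
  additionally receive twice the trial-to-trial heartbeat-locked response
  variability (zero-mean per-beat amplitudes, SD 2 uV), the mechanism
  behind the whole-protocol HER-variance contrast.

What the generator does **not** emulate: realistic ECG morphology beyond a
peaked template, ocular/muscle artifacts, non-stationary vigilance drifts,
per-subject montage digitisation error, and volume-conduction forward
models. Passing tests therefore demonstrate that the statistical machinery
behaves correctly on data with the right first-order structure; they do not
certify performance on clinical recordings.

## Scaled study conditions

The verification studies run at sizes chosen to exercise the full pipeline
in minutes on one core; each is a deliberate scale-down of the full
protocol, with the trial structure intact:

* *Oracle equivalence*: 4 vs 4 subjects on 6 mutually neighbouring channels
  x 5 samples; all 70 partitions enumerated and compared with an
  independently coded brute-force implementation, exactly.
* *Type-I calibration*: 200 null cohorts, 20 vs 20 subjects, 16-channel
  grid, 50-sample maps, 500 partitions; the dataset-level false-positive
  rate is checked against [0.02, 0.10].
* *Planted recovery*: 20 cohorts of 18 vs 18 subjects, 48-channel cap,
  2+2 blocks x 40 trials, 500 partitions; significant clusters must overlap
  the planted windows, and the global effects must be significant (at
  0.05/8) only in the MCS-like group.
* *Surrogate specificity*: 10 runs per scenario of 12 vs 12 subjects,
  5 x 5 grid, 2+2 blocks x 40 trials, 50 surrogates x 500 partitions.
  Smaller cohorts put the rank-sum statistic at a low ceiling that smooth
  surrogate maps tie too easily, and fewer trials leave surrogate maps so
  noisy that their magnitudes rival true effects; both choices avoid
  those degenerate regimes, not any particular test outcome.
* *R-peak fidelity*: 20 single subjects, 24-channel cap, 1+1 blocks of 25
  trials, full ICA; detected peaks must match ground truth within one
  sample (4 ms) for at least 99% of beats with no false positives.
* *Classification*: feature tables at the full cohort size (46 vs 40)
  drawn from the combined-effect group pattern.

## Numerical choices and degenerate inputs

* Sample indexing is 0-based in all stored objects and files; epochs are
  half-open [lock, lock + L) windows; reported latencies are in ms.
* The neighbourhood distance comparison is inclusive (<= 4 cm).
* Rank computations use midranks; rank-sum variances carry the tie
  correction (computed once per dataset — ties are invariant under label
  permutation).
* Monte Carlo p values are plain proportions k/n without the +1 correction,
  matching the granularity of a 10,000-partition analysis; ties count as
  exceedances (the conservative convention).
* EDF output uses 16-bit scaling with per-channel physical ranges from the
  observed minima/maxima — lossless to well under 0.1 uV for uV-scale EEG;
  a trailing partial record is zero-padded and the true sample count stored
  in a reserved header field.
* Degenerate inputs fail loudly: all channels rejected, more than half the
  montage below the interpolation threshold, zero surviving epochs, an
  empty contrast side (named conditions in the error), all-zero median
  tests, constant correlation inputs.

## Limitations

The pipeline is validated against its own generator, not against clinical
data; absolute effect sizes, rejection tallies and classification
accuracies on real recordings will differ. The ICA is a FastICA variant
rather than the extended-infomax family, chosen for determinism and speed;
component selection is tuned to cardiac artifacts only. No paired designs,
no time-frequency analysis, no TFCE or cluster-mass statistics (the
max-|Z| statistic only), and no FDR alternatives to Bonferroni are
provided.
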