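---
title: "Detecting a theta/alpha phase code for serial order in working-memory electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a theta/alpha phase code for serial order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetaseq)
```

## The scientific question

During a Sternberg task a subject encodes a short list of letters, holds it
for a couple of seconds, and answers whether a probe letter was on the list.
Nested-oscillation models of working memory propose that the items held in
memory are reactivated serially within each cycle of a slow (theta/alpha,
7–13 Hz) rhythm: the first list item fires at an early phase of each cycle,
the second at a later phase, and so on, with fast broadband gamma power
(75–120 Hz) serving as a proxy for the local population spiking that carries
each item's representation.

`thetaseq` implements the full analysis chain needed to test this
hypothesis on multichannel intracranial recordings, together with a
synthetic-session generator that plants every effect the chain is designed
to detect, so that detection, calibration and recovery are all testable
without clinical data:

1. **Preprocessing** — polyphase resampling to 250 Hz, common-average
   re-referencing, DFT line-noise removal (60/120 Hz), epoching, and
   kurtosis-based rejection of epileptiform epochs.
2. **Time–frequency analysis** — sliding-window FFT power with
   frequency-adaptive 3-cycle Hanning windows below 30 Hz and a fixed
   100 ms window from 30–125 Hz, both stepped at 50 ms.
3. **Letter selectivity** — mutual information between encoding-period
   gamma power (70–100 Hz, baseline-corrected) and letter identity, with a
   label-permutation null and Bonferroni correction over electrodes × 120
   letter pairs; the better-driving letter of the winning pair is the
   site's *tuned* letter.
4. **Phase–amplitude coupling (PAC)** — magnitude-squared coherence
   between the raw maintenance signal and the 6-cycle Hanning power
   envelope of each amplitude frequency, averaged over three overlapping
   1 s retention segments and trials.
5. **The serial-order test** — instantaneous theta/alpha phase and
   smoothed fast-gamma power (Hilbert), 18 equal phase bins, per-position
   bin profiles averaged over sites, labelling of each bin by its
   maximal-power position, circular 6/6/6 template matching over all 18
   rotations, and a trial-label-shuffling permutation test.

## The synthetic session generator

`simulation_config()` fixes the study conditions. Trials follow the
Sternberg timing: three letters for 700 ms each, inter-stimulus intervals
drawn uniformly from 275–350 ms, a 2 s retention interval, then a probe.
Signals are built per channel from:

* **pink noise** (1/f, 10 µV SD) as the broadband background;
* a **theta/alpha sinusoid** (9 Hz by default) whose amplitude is lower
  during encoding (5 µV) than baseline (10 µV) and higher during
  maintenance (15 µV), reproducing the amplitude schedule seen at
  letter-selective sites;
* **gamma burst packets** — Hanning-windowed tone packets 2–3 cycles long
  with carriers drawn from 75–120 Hz. Packets avoid sharp edges so the
  rhythm stays sinusoidal and planted coupling cannot be mimicked by
  waveform asymmetry (the peak-locked control below verifies this);
* a **sustained induced-gamma response** to the tuned letter at selective
  channels, scaled so tuned-letter encoding band power is
  `tuned_gamma_gain` × the channel's background band power. Single-trial
  response power is lognormal (`response_power_sdlog = 0.8`): real
  broadband gamma is heavy-tailed across trials, and the 256-bin MI
  estimator depends on that skew (see below);
* **maintenance bursts**, one candidate per theta cycle. In trials whose
  list contains the channel's tuned letter, the burst phase is drawn from
  a von Mises distribution centred on that trial's list-position phase
  centre with concentration `phase_concentration`; in all other cases the
  phase is uniform. With concentration 0 nothing is planted and the burst
  phases are circularly uniform;
* rare **high-kurtosis biphasic transients** emulating epileptiform
  discharges (rate `artifact_rate_per_trial`).

Every planted parameter is returned as ground truth (per-channel tuned
letters, per-trial positions, every burst with its phase, artifact times),
and identical seeds give bit-identical sessions.

Two default choices deserve explanation:

* **Position phase centres** default to one slow-gamma (~50 Hz) subcycle
  of separation (1.2, 2.33, 3.46 rad). If the three positions were spread
  uniformly over the full cycle, the position-specific envelope phases
  would cancel exactly in trial-averaged PAC — coupling would be invisible
  at the session level even though each trial is strongly modulated. The
  subcycle spacing is what nested-oscillation accounts predict and keeps
  both the PAC and the ordering analyses sensitive.
* **`tuned_gamma_gain` defaults to 10.** Letter-selective sites are rare
  (the motivating data found 14 of 1,315) and strongly driven; the
  generator's selective channels represent those rare sites. With
  realistic sample sizes the 256-bin MI procedure needs an effect of
  roughly this size to clear a Bonferroni correction over electrodes × 120
  pairs (see the power analysis in the selectivity tests).

What the generator does **not** emulate: volume conduction and spatially
correlated noise across channels, non-stationary theta frequency drift,
eye/muscle artifacts (only spike-like transients are planted), set-size
variation, and genuinely nonsinusoidal rhythms. Passing tests therefore
demonstrate that the estimators recover planted effects under the stated
noise model, not that real recordings satisfy that model.

## A worked example

```{r example, eval = FALSE}
library(thetaseq)

session <- simulate_session(simulation_config(
  sampling_rate_hz = 250, n_trials = 60, n_channels = 4,
  selective_channels = 1, tuned_positions = rep(1:3, length.out = 60),
  rng_seed = 1))

rec <- preprocess_recording(session$recording)        # CAR + line filter
power <- letter_band_power(rec, session$events)       # encoding gamma
sel <- detect_selective_sites(power, n_perm = 40000, seed = 2)

maint <- epoch_recording(rec, session$events, "probe_onset", c(-2, 0))
pac <- pac_spectrum(maint, channel = 1)
band_pac(pac)                                          # 7-13 x 75-120 mean

pos <- session$truth$tuned_positions
tp  <- pos[!is.na(pos$position), ]
ord <- serial_order_permutation_test(maint, tp, n_shuffles = 1000,
                                     seed = 3,
                                     analysis_window = c(-1.85, -0.3))
glance(ord)
autoplot(ord$profile)
```

## Statistical and numerical choices

**Band-passing and instantaneous phase.** Phase and gamma power use a
frequency-domain construction: the FFT is multiplied by a band indicator
with 1 Hz raised-cosine edges, negative frequencies are zeroed, and the
inverse transform yields the band-limited analytic signal. This is exactly
zero-phase — any phase bias would corrupt a phase-code analysis — and
stable for any band below Nyquist. A forward–backward FIR filter would
need ~275 taps for a 7–13 Hz passband at 250 Hz, longer than a 387-sample
maintenance epoch can support. Phase 0 is the positive peak of the
theta/alpha component (cosine convention) everywhere in the package; the
template maximum over rotations makes the final ordering statistic
independent of this reference.

**Epoch conventions.** Epochs are half-open `[start, end)` with
`floor((end − start) × rate)` samples: the maintenance window −1.85 to
−0.3 s before the probe is 387 samples at 250 Hz. Analysis windows in
`phase_bin_profile()` can be narrower than the epoch so the Hilbert
transform's edge samples are discarded.

**TFR normalization.** Windowed Fourier coefficients are divided by the
taper sum and doubled, so a unit-amplitude sinusoid has power 1 regardless
of window length. Only baseline-corrected or relative power is used
downstream, so the absolute convention is free. Window centres whose
window would leave the epoch are dropped, not zero-padded. 30 Hz, where
the adaptive and the fixed scheme coincide (3/30 s = 100 ms), is carried
by the adaptive scheme.

**Mutual information.** MI uses 256 equal-width bins over the pooled
min–max range (plug-in estimator, 0·log 0 := 0, constant input defined as
MI 0). Two properties of this estimator shaped the implementation:

* *Resolution.* With one scalar per presentation and realistic trial
  counts (8–35 per letter), nearly every pooled value occupies its own bin
  and the estimator saturates at H(label) = 1 bit for any labelling — the
  permutation test then has no resolution at all. The selectivity input is
  therefore time-resolved: each presentation contributes its ~7 windowed
  power samples from 0.2–0.5 s, and the permutation relabels whole
  presentations (blocks), preserving within-presentation dependence. A
  per-presentation scalar path remains available
  (`letter_band_power(resolution = "trial")`).
* *Cross-pair comparability.* The estimator's bias tracks each pair's own
  occupied-bin count, and a real effect compresses the pooled binning, so
  raw MI systematically under-ranks truly selective pairs. The best pair
  is therefore selected by the permutation *z*-score (observed MI
  standardized against a screening null with the binning fixed), which is
  bias-matched across pairs. The reported p-value is still the plain
  permutation p of that pair — exact enumeration when the block count
  allows, otherwise Monte-Carlo with the add-one rule — Bonferroni-
  corrected by channels × pairs.

**PAC estimator.** Coupling is magnitude-squared coherence, estimated by
accumulating cross- and auto-spectra over the three 1 s retention
segments (50% overlap) of every trial; envelopes are mean-subtracted per
segment so their DC does not dominate. The bound in [0, 1] and invariance
to amplitude scaling follow by construction. Segments are clipped to the
samples where the 6-cycle envelope exists; for amplitude frequencies below
~15 Hz this shortens segments noticeably, which raises the variance of
those cells — one reason the null maximum over the full matrix is several
times its median even for independent noise. Encoding-period PAC is
refused by the pipeline (stimulus-evoked transients masquerade as
coupling) unless explicitly forced.

**Serial-order permutation test.** Surrogates permute the position labels
among each site's qualifying trials (per-position counts preserved,
neural time series untouched) and recompute the entire profile → labels →
template fit chain; p is the proportion of surrogate fits ≥ the observed
fit, the literal rank rule, with no add-one term (the selectivity module's
Monte-Carlo test does use add-one; the difference is intentional and
documented here). Because the fit statistic is an integer in [6, 18] —
its mean over the 18 rotations is exactly 6 for any labelling — the
p-value is conservative under heavy ties: with a single site the null
false-positive rate at α = 0.05 is essentially 0. Averaging profiles over
≥ 4 sites restores calibration (measured false-positive rate ≈ 0.05).
Argmax ties in bin labels go to the smallest position; template-fit ties
go to the smallest rotation index.

**Preferred-phase recovery.** The preferred phase of each position is the
circular mean of bin-centre phases weighted by that position's mean power:
a phase-uniform background adds no net direction, so the estimate is
unbiased for the planted centre. Two half-sample centring subtleties
matter at this precision: smoothing kernels and burst packets are forced
to odd lengths, because an even-length kernel applied with
`stats::filter(sides = 2)` sits half a sample off-centre, which alone
biases recovered phases by ~0.1 rad at 9 Hz.

**Degenerate inputs.** All-zero spectra cannot be display-normalized;
zero-variance segments, empty band selections, constant reaction times,
windows outside the recording, and all-rejected epoch sets raise errors
naming the offending object. A paired t test with identically zero
differences reports t = 0, p = 1, d = 0 rather than failing.

## Problem sizes

The test-suite and acceptance runs use synthetic sessions at the analysis
rate (250 Hz) with 30–160 trials and 1–14 sites; permutation counts are
1,000 shuffles for planted-effect recovery, 500 for the 100–200-run null
calibrations, and up to 40,000 Monte-Carlo label permutations where a
Bonferroni correction over 480 channel-pairs must be cleared. These sizes
were chosen so each property is measured at the smallest scale at which
it is statistically meaningful.

## Known limitations

* The MI selectivity procedure needs strong effects to clear its
  Bonferroni correction at realistic trial counts; weakly selective sites
  (gain ≲ 4) are usually missed. This mirrors the rarity of such sites in
  the motivating data rather than a fixable implementation detail.
* With few recording channels the common average reference leaks a
  fraction of a strong selective response into the other channels, which
  can make them weakly letter-dependent; with clinical channel counts
  (hundreds) the effect is negligible.
* Session-level PAC presumes the position phase centres span less than
  the full cycle; a planted code with centres uniform over the cycle is
  detectable by the ordering test but invisible to trial-averaged PAC.
* The serial-order p-value is conservative for single sites (integer fit
  statistic, heavy ties).
* EDF and HDF5 containers are not read or written; sessions are
  serialized as TSV + JSON (`write_session()`/`read_session()`).
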