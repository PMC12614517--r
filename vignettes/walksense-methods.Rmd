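---
title: "Methods: contactless gait metrics from skeleton streams and floor vibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless gait metrics from skeleton streams and floor vibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

walksense estimates gait speed (m/s) and cadence (steps/min) during hallway
walking trials from two contactless modalities — a depth-camera body tracker
streaming 32 joint positions at about 30 fps, and an array of seven
floor-mounted single-axis accelerometers sampled at 16,384 Hz — and provides
the statistics needed to qualify such a system: test–retest reliability,
device-versus-stopwatch validation, and outcome models. This vignette
explains the models, the tunable parameters, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## Trial geometry

A trial is a 14 m walk between two marked lines. The first and last 3.5 m
are acceleration and deceleration zones; the central 7 m monitored zone is
where walking is steady-state (`trial_config()`). Six sensors form a 2 × 3
grid (5.0 m along-hallway by 3.5 m across-hallway spacing); a seventh is
co-located with one of them but wired to the *other* data-acquisition unit
(DAQ), because the two wireless DAQs run independent clocks.

## Camera pipeline

**Speed.** The pelvis displacement at frame $i$ is
$d_i = \lVert p_i - p_0 \rVert_2$, the 3-D distance from the first tracked
pelvis position. Being a norm of coordinate differences, $d_i$ — and
therefore speed and cadence — is invariant to the camera's pose: joint
coordinates are used in the camera frame as-is. Gait speed is the slope of
the least-squares line $d_i = g_s t_i + d_0$. Tracking dropouts (all three
coordinates of a joint missing; zeros are legal coordinates, so `NA`
triplets are the sentinel) are handled by `clean_distance()`: leading and
trailing dropout runs are removed, interior runs of ≤ 2 samples are linearly
interpolated, and longer interior runs split the series, keeping the longest
clean segment with a flag. Because trials include acceleration tails, the
fit is trimmed iteratively — one sample off each end per iteration (the
smallest symmetric step; the trimming granularity is otherwise arbitrary) —
until $R^2 > 0.98$, with a floor of `min_points = 30` samples (~1 s at
30 fps) below which the fit is flagged `trim_failed` rather than trimmed
further. This flag is an automated stand-in for the manual review such
trials would otherwise need. $R^2$ is the squared Pearson correlation,
identical to the OLS coefficient of determination for a simple linear
regression, and defined as 0 for degenerate (constant) input.

A boundary worth knowing: with noiseless *standing* tails the overall
$R^2$ can sit just above 0.98 (for 1 s tails around a 7 m walk it is
≈ 0.988), in which case the rule correctly performs no trimming and the
slope retains a low bias of several percent. With acceleration-ramp tails
of the kind the protocol produces, the bias stays under 2 % across
0.4–1.8 m/s. Raising `r2_threshold` trims harder at the cost of using
fewer samples.

**Cadence.** The foot-swing signal per side,
$FS_i = \lVert \text{ankle}_i - \text{pelvis}_i \rVert_2$, cancels body
translation and oscillates at the *stride* frequency (each foot strikes
once per stride; one stride = two steps). Each side is mean-removed,
resampled by linear interpolation to a uniform grid at the median frame
interval (camera timestamps jitter), zero-padded to at least 100 s so the
frequency grid is no coarser than 0.01 Hz (1.2 steps/min), and Fourier
transformed. The dominant magnitude within the search band — default
0.5–1.5 Hz, i.e. 60–180 steps/min, with ties broken toward the lowest
frequency — gives $f_{\max}$ per side, and cadence is
$120 \cdot \mathrm{mean}(f_{\max}^L, f_{\max}^R)$. The factor 120 (two
steps per stride, 60 s/min) pins the interpretation: the per-foot dominant
frequency is the stride frequency, not the step frequency.

**Body dimensions.** Torso length is taken as pelvis→neck (the specific
joints are a documented choice; the tracker offers several spine points),
leg length as hip→knee plus knee→ankle averaged over sides, shoulder width
as the inter-shoulder distance; each is the median over frames (robust to
swing-phase geometry), body length = torso + mean leg, body area =
shoulder width × body length. Cohort body areas are standardized against
the female subgroup mean and SD.

## Floor pipeline

**Preprocessing.** Each channel is linearly detrended, high-passed at 5 Hz
and low-passed at 250 Hz (Butterworth, order 2, each applied
forward–backward). The forward–backward pass squares the magnitude response
and cancels phase, so impulse timing is preserved exactly — a property the
suite asserts by checking that an isolated impulse's peak-energy window is
identical before and after.

**Synchronization.** The lag of the maximum cross-correlation between the
co-located pair estimates the inter-clock offset; all channels of the
second DAQ group are shifted by it and the redundant duplicate sensor is
dropped. The correlation is computed with zero-padded power-of-two FFTs
(mixed-radix FFTs on awkward lengths are prohibitively slow) and is exact
to the sample.

**Detection.** Mean signal power (acceleration²) is computed per sensor in
non-overlapping 0.02 s windows and divided by that sensor's median window
power. This median normalization makes every sensor's SNR series — and
everything downstream — invariant to per-channel gain. `SNRmax` is the
per-window maximum across sensors. Peaks are local maxima at least
$\mathrm{median}(SNR_{\max}) + 9\,\sigma_{SNR}$ high, where
$\sigma_{SNR}$ is the SD after one-sided exclusion of points more than
3 raw MADs above the median (footstep peaks are positive excursions and
must not inflate the noise estimate; raw MAD, constant = 1, matches the
convention of the numerical environment such pipelines are usually built
in). Retained peaks must be ≥ 0.3 s apart; suppression is greedy,
highest peak first, which is the semantics common peak finders implement.

**Cadence.** Inter-peak intervals $\Delta t$ estimate step times; missed
steps or pauses appear as long-interval outliers. Intervals outside
median ± 3 raw MADs are removed; when the MAD is 0 (perfectly periodic
synthetic steps) intervals above 1.5 × the median are removed instead.
Cadence is $60 / \mathrm{mean}(\Delta t)$ on the survivors. The per-gap
instantaneous cadence $60/\Delta t$, z-scored within trial, is the
detection-quality diagnostic: a missed step shows as a precipitous
negative z.

**Localization and speed.** Footstep energy is modeled as decaying
exponentially with distance: $\log E_s = \log E_0 - \alpha\, d_s(u)$.
Energies are integrated over ±0.05 s around each detected step and
normalized by the sensor's noise-floor (median window) energy, which both
cancels per-channel gain and absorbs sensitivity differences; when the
noise floor is exactly zero (noiseless synthetic input) the normalization
is skipped. Positions are solved in 1-D along the hallway axis, with the
walking line's across-hallway offset absorbed into the effective distance
$d_s(u) = \sqrt{(u - u_s)^2 + (v_w - v_s)^2}$: a 2-D solve is
underdetermined with six usable sensors and noisy decay. Because floors
are not homogeneous media, $\alpha$ defaults to a per-trial fit: each step
is first fitted with a free slope over a 0.02 m position grid, the trial
$\alpha$ is the median of the per-step estimates, and positions are
re-fitted at that common $\alpha$ (profile least squares, refined by 1-D
optimization). Speed then comes from a constant-speed Kalman filter over
the step positions with Rauch–Tung–Striebel smoothing: measurement
variance from the residual MAD of a robust (M-estimator) line pre-fit,
small process noise on speed (walking is quasi-constant), and an
innovation gate at 9 (3σ) that skips observations localized far off the
track — the mechanism that corrects gross mislocalizations. If the pre-fit
underestimates the noise so badly that over 30 % of observations are
gated, the measurement variance is inflated and the filter rerun. The
reported speed is the OLS slope of the smoothed positions (equal to the
terminal smoothed speed on a constant-speed walk); in the full pipeline it
is fitted only over steps localized inside the monitored zone, which is
precisely what that zone is for.

## The synthetic walker

`simulate_trial()` generates both modalities with shared ground truth. The
walker accelerates over `tail_s` (default 1 s), cruises, and decelerates
symmetrically; heel strikes occur at the cadence interval with positions
taken from the motion profile, so cruise-phase spacing equals the step
length (speed = cadence/60 × step length) exactly while the tails show the
shorter steps of an accelerating walker. The pelvis carries small vertical
(step-frequency) and lateral (stride-frequency) oscillations; ankles swing
about the pelvis at the stride frequency with alternating phase, the
vertical component dominating the foot-swing oscillation. Tracking noise is
Gaussian per coordinate (default 5 mm), frames drop out independently
(default 2 %) plus forced leading/trailing runs, and timestamps jitter by
1 ms. Each heel strike injects a Gaussian-windowed 80 Hz sinusoid (inside
the 5–250 Hz passband; envelope SD 8 ms) into every sensor with amplitude
$\propto e^{-\alpha d / 2}$ so energy decays as $e^{-\alpha d}$
(default $\alpha$ = 0.4 /m), plus white sensor noise; the second DAQ
group is delayed by `daq_lag_s`. Defaults emulate the adult preoperative
cohort the protocol targets: 1.2 m/s, 111 steps/min, with 0.4–1.8 m/s and
81–152 steps/min as the tested ranges.

`simulate_cohort()` draws subject-level speed (mean 1.2, SD 0.27 m/s) and
cadence (mean 111, SD 11 steps/min) with age effects carved out of the
marginal SDs, 66 ± 13 years of age and 60 % male; two trials at each of
two paces, fast pace scaling speed ×1.25 and cadence ×1.14; device
measurements add small noise, stopwatch measurements add 0.3 s reading
error with occasional gross misreads; body area places men ~1.5
female-SDs above the female mean; frailty scores rise monotonically as
gait slows; good recovery is generated from the standardized
speed × cadence interaction, so the interaction model has a recoverable
signal.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: inhomogeneous floor media (real energy decay
is not cleanly exponential, and localization noise is structured rather
than Gaussian), multi-person or off-line walking, asymmetric or pathologic
gait, correlated tracker noise and occlusion-driven dropout bursts,
reverberation and overlapping footstep transients, and non-Gaussian
accelerometer noise. The validation statistics are exercised on synthetic
cohorts whose generating assumptions (Gaussian subject effects, monotone
frailty link) are idealized.

## Reliability and validation statistics

Test–retest reliability is the single-measure intraclass correlation from
the ANOVA mean squares. The default form is one-way random effects,
ICC(1) — the default of the commonly used reliability packages, hence the
most probable original computation — with two-way consistency ICC(C,1) and
agreement ICC(A,1) selectable; p-values are the McGraw & Wong F tests. The
permutation check shuffles the second trial across subjects (breaking
pairing, preserving marginals) 10,000 times by default and reports
$Q = (b + 1)/(n_{perm} + 1)$, never exactly zero. No multiple-testing
adjustment is applied anywhere; Q and p are reported raw.

Device-versus-stopwatch comparison first drops pairs with stopwatch speed
> 2.5 m/s (implausible walking; a misread), then pairs whose
device−stopwatch difference is beyond 2.5 SDs of the difference
distribution, and reports Pearson r on the survivors. Leave-one-out
logistic prediction refits a single-feature model per held-out subject;
accuracy uses a 0.5 threshold and AUC is the rank (Mann–Whitney) statistic
on held-out probabilities with ties averaged; folds losing a class are
flagged and skipped. Fried scores map 0 → robust, 1–2 → prefrail,
> 2 → frail; QoR-15 > 121 is good recovery (strictly greater; 121 itself
is poor). The recovery model is
`outcome ~ speed + cadence + speed:cadence`, reporting the interaction
odds ratio with a Wald 95 % CI, runnable for any device combination
supplying the two metrics; separation is flagged with a suggestion to
refit penalized rather than silently reported.

## Problem sizes and numerical checks

The test suite exercises: speed recovery on a 15-point grid over
0.4–1.8 m/s (7 seeds per point, 2 % tolerance at 95 % coverage); cadence
on 81–152 steps/min against a 1 FFT-bin (camera) and 1 steps/min (floor)
tolerance; detection completeness on 100 clean trials at 4,096 Hz with
100 step-free noise trials for false positives; clock-offset recovery on
50 trials at 16,384 Hz to one sample; Kalman tracking on 100 noisy tracks
(σ = 0.3 m) at 15 % tolerance and noiseless tracks at 10⁻⁶; the ICC
against `aov()` variance components on 1,000 random tables at 10⁻¹⁰;
LOOCV against a brute-force per-fold refit, prediction-identical; and a
200-subject cohort rehearsal recovering the fast-pace scaling factors
within 2 % and the device-ICC > stopwatch-ICC ordering. Simulation sizes
were chosen as the smallest that make these properties sharp; the
vibration checks run at 4,096 Hz where the property under test does not
depend on the native 16,384 Hz rate.

## Known limitations

The trimming rule inherits the $R^2$ threshold's blind spot described
above. Localization degrades outside the sensor span (positions near the
hallway ends are extrapolations of the decay model) — the monitored-zone
restriction sidesteps this for speed, but per-step positions printed for
end-zone steps should be treated with caution. The decay-constant fit
assumes one $\alpha$ per trial; strongly heterogeneous floors violate
this. The ICC form actually used by any given prior analysis is not
knowable from its text; both one-way and two-way forms are exposed so the
choice is explicit.
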