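---
title: "Event-locked arousal and vocalisation analyses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked arousal and vocalisation analyses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dyadarousal` analyses how autonomic arousal co-fluctuates with the timing of
vocalisations in caregiver–infant dyads recorded over day-long sessions. The
data model is deliberately coarse: one 60-s epoch is the time unit, each
participant contributes a z-scored composite arousal value per epoch, and
vocal events are points on the same epoch grid, detected by a duty-cycled
microphone that samples 5 s of every minute (8% of the day). This vignette
documents the models, the inferential machinery, the synthetic-data
generator, and the numerical conventions, in that order.

## The data model

**Epochs and masks.** All series live on a uniform grid of 60-s epochs,
indexed from 0, with half-open intervals. A validity mask marks the epochs
that enter analysis (in the motivating design: the dyad at home and the
infant awake; naps and outdoor transport are excluded in contiguous blocks).
Invalid epochs carry no values — undefined quantities are `NA` throughout,
never silently 0.

**Composite arousal.** Each participant's arousal is built from up to three
autonomic channels per epoch — heart rate, heart-rate variability, and
movement (actigraph magnitude). Each channel is sign-oriented so that higher
means more aroused (heart rate +1, HRV −1, movement +1), z-scored over its
own valid epochs, averaged across whichever channels are observed at each
epoch, and the average re-z-scored. Because z-scoring is within-person over
the analysed day, 0 is that participant's day-average arousal, which is the
chance level against which event-locked trajectories are tested.

**Autocorrelation removal.** Arousal is strongly autocorrelated at the
1-min scale, which would leak into any event-locked average. Before the
trajectory analyses the package residualises each series with a first-order
autoregression fitted by ordinary least squares over consecutive valid
pairs, then re-z-scores. Gaps in the mask break pair formation, so the first
epoch of each valid run has no residual and becomes invalid. This is the
minimal model consistent with the strong first-order autoregressive
tendency of epoch-level arousal; richer prewhitening (higher AR orders,
state-space filters) is deliberately out of scope.

## The analyses

**Temporal clustering (likelihood profiles).** For each reference event at
epoch $t$ and relative-time bin $[a, b)$ minutes, we score an indicator that
at least one target event lies in epochs $[t+a, t+b)$, and average over
reference events. Bins are 2 min wide with edges at odd minutes
($\ldots, [-3,-1), [-1,1), [1,3), \ldots$) spanning ±20 min, so that
"1–3 min after" is exactly one bin. A bin contributes for an event only if
at least one of its epochs is observable. The chance profile comes from
matched control events: for each dyad, pseudo-events drawn uniformly
without replacement from valid epochs carrying no vocalisation by either
partner, with exactly as many pseudo-events as real events, repeated
`n_control_reps` times (1000 by default) and averaged.

**Event-locked arousal.** The trajectory is the mean of the (prewhitened)
arousal at lags −20…+20 min around each event, per participant. Because the
series is z-scored within person, the group test compares the trajectory
with 0 at each lag.

**Arousal peaks.** Peak epochs are those whose arousal strictly exceeds the
participant's 100−pct percentile over the day (pct = 10 as the main
threshold, 5 and 20 as robustness settings). The likelihood of vocalisations
around peaks is then profiled exactly as above, with controls drawn from
valid, non-peak, non-vocalisation epochs.

**ROC prediction.** Per dyad, every valid epoch is labelled by vocalisation
presence and the arousal value is swept over all observed thresholds; the
area under the resulting ROC curve (trapezoidal) measures how well arousal
alone predicts vocalisation timing. The sweep is algebraically identical to
the rank-sum probability-of-correct-ordering formulation with ties counted
0.5 — a tested invariant. Group inference compares the per-dyad AUCs with
the chance value 0.5.

**Partner-arousal quartile split.** Events are subdivided by the
vocaliser's arousal at the event epoch into within-participant quartiles
(rank-based, stable ties on epoch index), and the partner's event-locked
trajectory is averaged per quartile and time bin. Per bin, a one-way ANOVA
on the participant-level quartile means asks whether the partner's response
depends on the vocaliser's arousal.

**Arousal stability and coupling.** Both are moving-window statistics with
window W = 10 epochs and shift S = 5 (the window centre is the epoch
$i + \lfloor W/2 \rfloor$). Stability is the lag-1 Pearson autocorrelation
of one participant's arousal within the window; coupling is the Spearman
correlation of the two partners' independently linearly detrended arousal
over jointly valid epochs — a zero-lag synchrony index. A window needs at
least `min_valid` = 5 valid (jointly valid, for coupling) observations,
else its value is undefined; 5 of 10 was chosen so that a majority of the
window is observed. Windowed values are excerpted around events by
nearest-centre lookup (ties to the earlier window) and compared with the
same excerpt around control events.

## Group inference

**Mann-Whitney with Hodges-Lehmann effect sizes.** Real-vs-control
contrasts across participants use the two-sided Mann-Whitney U test; the
effect size is the Hodges-Lehmann estimate, the median of all pairwise
real − control differences. The p-value is exact (from the null
distribution of U) when the combined sample is ≤ 20 without ties, and a
tie-corrected normal approximation otherwise (no continuity correction;
the switch point keeps exact enumeration cheap while covering the sample
sizes where the approximation is weakest).

**Permutation-based temporal clustering.** Testing 21 bins or 41 lags
inflates false positives, and the effects of interest are temporally
contiguous, so the correction works on clusters: per bin a standardised
statistic z; bins with two-sided p < 0.05 form maximal runs of contiguous,
same-signed bins; each cluster's mass is its summed |z|; and the null
distribution of the *maximum* cluster mass is built by permutations that
respect the participant structure. Cluster p-values are
$(1 + \#\{\text{null max mass} \ge \text{observed}\})/(n_{perm}+1)$, which
can never be exactly zero. Three permutation schemes match the three
contrast types:

* *label swap* — real vs averaged-control profiles: each permutation swaps
  the real/control labels within a random subset of participants; the bin
  statistic is the tie-corrected Mann-Whitney z across participants.
* *sign flip* — trajectory vs 0: each permutation flips the sign of whole
  participant rows; the bin statistic is the Wilcoxon signed-rank z.
* *quartile relabel* — the quartile ANOVA: each permutation independently
  permutes each participant's quartile labels; the bin statistic is the
  normal score of the one-sided F p-value.

The cluster statistic (sum of |z| over supra-threshold bins, sign-homogeneous
clusters only) follows common neuroimaging practice; sign homogeneity keeps
a cluster interpretable as one directional effect. Type-I calibration of the
label-swap test is verified by simulation in the test suite (500
exchangeable-null cohorts of 20 participants × 20 bins at 200 permutations;
the family-wise rate must fall in [0.03, 0.08] at α = 0.05).

## The synthetic dyad generator

Day-long home recordings of this kind are not freely shareable, so the
package ships a forward model that generates dyads with the statistical
structure the analyses assume, making every downstream stage testable.

**Latent arousal.** The two partners' arousal follows a bivariate AR(1):
own persistence $\phi$ per partner, innovation SD $\sigma$, and a
cross-coupling parameter $\kappa$ per direction. Coupling acts *within* the
epoch: the update is $a_t = M(\Phi a_{t-1} + u_t + \varepsilon_t)$ with
$M = (I - K)^{-1}$, $K$ holding the two $\kappa$'s off-diagonal. This
represents co-regulation faster than the 60-s sampling; it induces both
lagged cross-influence (the effective lag matrix $M\Phi$, validated for
spectral radius < 1) and positive zero-lag synchrony. The design was
deliberate: a purely lagged cross-term at epoch resolution produces
*negative* detrended zero-lag correlation — the windowed coupling statistic
weighs fast fluctuations, where a lag-1 cross-term alternates in sign — so
a generator with lagged-only coupling cannot reproduce the positive
synchrony it is meant to emulate. Stationarity still constrains the
parameters: with symmetric coupling the effective persistence is
$\phi/(1-\kappa)$, so e.g. $\kappa = 0.5$ requires $\phi < 0.5$; the
coupling-recovery experiments use $\phi = 0.4$ in both arms.

**Vocal events.** Per epoch and speaker, at most one event is emitted with
log-odds
$\beta_0[s,c] + \beta_{self}[s,c]\, z_{own} + \beta_{partner}[s,c]\, z_{partner} + \gamma\,[\text{own event in last } k \text{ epochs}]$,
with arousal standardised to unit stationary variance so the slopes are per
z-unit. The self-excitation term $\gamma$ (memory $k$ = 3 epochs) creates
temporal clustering; if several categories fire in one epoch, cry takes
priority over speech-like over other. Events occur only on valid epochs —
the microphone cannot detect a vocalisation during excluded time.

**After-effects.** Infant events feed a boxcar impulse $u_t$ back into the
infant arousal input: cries add a negative impulse for 5 epochs
(down-regulation), speech-like events a positive one for 10 epochs
(sustained elevation). Through the within-epoch mixing a fraction of the
impulse reaches the caregiver, mimicking a caregiver response.

**Mask and duty cycle.** The validity mask removes a fraction of epochs in
a few contiguous blocks (naps, outdoor transport), not i.i.d. epochs. The
duty-cycled detector emits an event for an epoch iff a continuous-time
vocal interval overlaps the 5-s snapshot at the start of that minute;
`events_to_intervals()` gives each vocal minute a realistic interval (cry
bouts 5–30 s, speech-like utterances 1–5 s, other/caregiver 1–8 s, onset
uniform within the minute, spill-over into the next minute allowed) so the
fidelity of sparse sampling can be studied.

**Presets.** `scenario_params()` ships three scenarios. `"null"` keeps
realistic base rates but removes every dependence — all detectors should
reject at their nominal rate. `"paper_like"` combines persistent coupled
arousal ($\phi = 0.75$, $\kappa = 0.08$), arousal-contingent vocalising
that is stronger in the infant ($\beta_{self}$ 1.2 for cries, 0.8 for
speech-like) than the caregiver (whose events instead track the *infant's*
arousal, $\beta_{partner} = 0.6$), self-excitation $\gamma = 0.8$, and
category-specific after-effects. Baseline rates are calibrated only to the
typical infant category proportions (roughly 3 cries : 6 speech-like : a
handful of rare others); absolute per-hour rates are not well constrained for this
kind of recording and were fixed once at plausible values (≈ 0.01 cry /
0.075 speech-like baseline probability per epoch). `"cry_vs_speech"`
emphasises the post-event contrast (cry impulse −0.8, speech +0.4).
Defaults put 240 epochs per dyad with 92% validity, i.e. ≈ 220 valid 1-min
epochs — a typical at-home, awake day.

**One master seed.** Every stochastic component (mask, innovations, event
draws, control resampling, permutations) derives its stream
deterministically from one seed, so identical parameters and seed
reproduce a dyad — and a whole pipeline run — bit for bit.

**What the generator does not emulate.** Circadian structure, affect and
intensity beyond the categorical label, channel-level measurement noise and
artefacts, informative (arousal-dependent) masking, caregiver vocal
subtypes, and acoustic content. Passing the suite therefore shows that the
estimators and tests behave correctly under the assumed structure — not
that the substantive findings generalise to real recordings.

## Numerical conventions and degenerate inputs

* Percentiles use R's default linear-interpolation convention (type 7);
  peak detection is strictly `>` the threshold, so threshold ties are not
  peaks, and for all-distinct values the peak count is within rounding of
  n·pct/100.
* Rank correlations use average ranks for ties.
* Windows with fewer than `min_valid` usable pairs, residuals that vanish
  (exactly linear windows, at a relative tolerance of 1e-10), and lags with
  no contributing events are all `NA`, and `NA` propagates — means are
  taken over defined values with the contributing count reported.
* Constant channels and empty masks are errors naming the offending input,
  not warnings.
* The Mann-Whitney exact/approximate switch is at combined n = 20; the
  permutation p-value convention `(1+k)/(1+n_perm)` avoids zero p-values.
* Epochs are 0-based half-open everywhere; timestamps are seconds from
  session start.

## Problem sizes

The test suite and the calibration experiments run at sizes chosen to make
Monte-Carlo error small relative to the tolerances being checked while
keeping a full run on one CPU comfortable: 200 dyads for the null ROC
calibration, 500 cohorts × 200 permutations for cluster type-I calibration,
100 cohorts of 20 dyads for effect recovery, 50 + 50 dyads for coupling
recovery, and 50 dyads for the sparse-sampling fidelity check. The analysis
scripts under `analysis/` use 20-dyad cohorts with 100 control sets and 500
permutations; `run_config()` defaults to the full 1000/1000 used by the
motivating design.

## Known limitations

* The AR(1) residualisation removes only first-order structure; slow
  non-stationary drift (e.g. time-of-day effects) would survive both the
  prewhitening and the within-person z-scoring.
* Control events are matched in count but not in local context (e.g. time
  of day), which is faithful to the resampling design
  but means controls inherit no circadian structure.
* The quartile ANOVA treats quartile as a categorical factor; a monotone
  trend test would be more powerful against ordered alternatives.
* With very sparse events (a handful per dyad) the per-dyad profiles are
  noisy and dyads fall below the usable-event thresholds; the pipeline
  reports exclusions rather than imputing.
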