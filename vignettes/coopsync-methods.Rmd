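---
title: "coopsync: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coopsync: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `coopsync`: the generative
models, the analysis chain, every tunable parameter that matters, and the
design decisions taken where the problem left the design open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The task and its behavioural statistics

Two partners press keys after a shared go signal; a trial is won when the
absolute reaction-time difference `RTD = |RT1 - RT2|` is at most the
trial threshold `T = (RT1 + RT2)/8`. The threshold is computed from the
*current* trial's reaction times — the task description ties the
threshold to each trial's RTs ("the longer the RTs ... in each trial, the
greater the threshold"), so no running average is used. Whether an exact
tie wins is ambiguous in the source descriptions (one passage says
"less than or equal to", another "less than"); the package defaults to
ties-win (`tie_rule = "leq"`) and exposes the flag.

Per dyad and session the package reports the winning ratio
`WR = wins / trials`, mean RT, mean RTD, mean threshold, and the
cooperation coefficient `CC = mean(T) - mean(RTD)`. Two identities are
enforced by construction and asserted in tests: the cumulative score
satisfies `WR = (final score + N) / 2N`, and `CC` is exactly the margin
between earned slack and wasted mismatch.

Reaction times are capped at the 4 s response window; a non-response is
modelled as an RT of 4 s rather than a separate missing state, since the
paradigm description never mentions missed trials. Trial onsets for the
signal timeline are placed using cue delay + slower partner's RT +
feedback (2.0 s) + inter-trial interval (1.5 s), chosen so 20 trials
fill roughly a 150 s block.

## 2. The strategy-structured generator

The simulator is hierarchical. For a dyad in strategy group `g`:

1. **Dyad mean RT** `mu_d` is drawn from a normal with the group's
   published mean and SD — delayed `0.83 ± 0.44 s`, immediate
   `0.30 ± 0.06 s`, none `0.43 ± 0.09 s` — truncated below at 0.05 s.
   The truncation parameters are *moment-matched*: the truncated
   distribution's realized mean and SD equal the configured values, so
   the generator reproduces the printed group statistics rather than
   biased versions of them. For the delayed group the implied deliberate
   delay `mu_d - 0.33` has median near 0.5 s, matching the reported
   average delay; the delay is shared at dyad level (both partners use
   the same rhythm), which is what distinguishes "delayed" from merely
   "slow".
2. **Dyad sloppiness** `f_d` is a mean-preserving log-normal factor
   (`cv_log = 1.0`). It scales the base trial noise as `sqrt(f_d)` and
   the slip magnitude as `f_d^1.5` (floored at 1, capped at 0.9 s).
   Couples therefore differ widely — the "failed strategy" dyads in the
   tails are real features of the paradigm (published WR SDs of
   0.17–0.21 imply strong dyad heterogeneity).
3. **Trial RTs** share a common component with weight
   `rho = within_dyad_coupling` (delayed 0.8 — a rehearsed rhythm;
   immediate/none 0.3 — coupling only through the stimulus), so
   `cor(RT1, RT2 | dyad) = rho` on regular trials.
4. **Slip trials** occur with probability `inconsistency_rate`
   (delayed 0.2, immediate 0.3, none 0.5): the partners drift apart by
   an antisymmetric offset `±delta/2`, `delta ~ N(0, slip_sd)`. Slips
   inflate the trial RTD without moving either partner's mean RT, which
   keeps the printed group RT means intact. The no-strategy group's
   regime mixing is modelled as this single mismatched-trial mode rather
   than four separate sub-cases.
5. A closed-form compensation subtracts the expected inflation from
   clipping RTs at the floor, so realized trial-RT means equal the
   configured group means to within Monte-Carlo error (asserted at 3 SE
   in the tests).

The free parameters (base noise SDs 0.18 / 0.044 / 0.09 s; slip sizes
0.46 / 0.50 / 0.22 s) were fixed once, by a design study run before the
acceptance tests were written, to reproduce the paradigm's behavioural
decomposition: thresholds ordered delayed > none > immediate with a
significant ANOVA, group RTDs statistically indistinguishable at the
cohort sizes 17/16/10, WR ordered delayed > immediate > none, and a
positive CC–WR correlation. The counter-intuitive slip-size ordering
(immediate dyads slip rarely but big, none dyads slip constantly but
moderately) is what equalises the group mean RTDs while preserving the
WR ordering — exactly the tension the decomposition describes: the
delayed group wins through larger thresholds, not smaller RTDs.

What the generator does *not* emulate: learning or adaptation across
trials (the paradigm reports none), feedback-driven RT adjustment, and
the four qualitative sub-types of the no-strategy group.

## 3. The two-brain signal model

Each participant × channel receives a true oxyhemoglobin series (µM):
1/f drift (`alpha = 1`, SD 1 — the reference amplitude unit), cardiac
(~1.0 Hz, 0.5), respiration (~0.25 Hz, 0.6), Mayer waves (~0.1 Hz, 0.8),
and white noise (0.3). The Mayer wave sits *inside* the 3.2–12.8 s
analysis band on purpose: it is an independent-phase confound present in
task and rest alike, so the task-minus-rest contrast is stress-tested
against it. HbR is generated as `-HbO/3` plus independent noise (the
typical hemodynamic anticorrelation); only HbO is analysed downstream.

Inter-brain coupling is a *narrowband stochastic oscillation* (white
noise shaped by a Gaussian profile of ±0.5 octave around a 6.4 s
period) — not a sinusoid, which would produce degenerate unit coherence.
It is added, scaled by `strength_by_strategy` (delayed 5, none 0.8,
immediate 0) times the 1/f SD, to the coupled channels (default: channel
19 only) during the task segments only, with cosine on/off ramps;
participant 2's copy can be lagged to create directional ground truth
for causality analysis. The delayed default is deliberately strong: the
30 s rest baseline makes the task-minus-rest contrast noisy (per-dyad
IBS carries an SD near 0.12 even for planted effects), and the default
world is meant to contain a reliably detectable effect at the target
channel, with the "none" group's 0.8 producing occasional uncorrected
significance but rarely surviving FDR.

Optics: hemoglobin is pushed through the modified Beer–Lambert law
(shared extinction table, DPF 6.0 both wavelengths, 3 cm separation,
conventional 690/830 nm defaults — the original device's wavelengths are
not stated anywhere, so these are configurable) to optical density and
intensity `I = exp(-OD)`, guaranteeing positive intensity. Because the
forward model and preprocessing share one constants module, the
round-trip is exact up to injected noise (tests assert r > 0.99 against
ground-truth HbO).

Motion artifacts are spikes (0.3–0.8 s Gaussian pulses) and *transient*
baseline shifts (4–10 s boxcars), 8–16 robust SDs, at Poisson times,
applied to all channels of the moving participant. Baseline shifts
return to baseline deliberately: the correction contract keeps unflagged
samples bit-identical, and a persistent step cannot be removed under
that contract. The ground-truth mask covers each artifact's full extent.

## 4. Preprocessing

* **Channel rejection**: raw-intensity `mean/SD < 2` (worse of the two
  wavelengths), computed over the whole recording on intensity (the
  common convention; whether the original analysis used intensity or OD
  is not stated). The ratio is gain-invariant. Rejected channels
  propagate as missing: a dyad's channel is analysed only when valid for
  both partners.
* **OD conversion**: `OD = -log(I / mean(I))`.
* **Motion detection**: a sample is flagged when its deviation from a
  20 s running-median baseline exceeds 5 robust SDs, or its
  sample-to-sample slope exceeds 80 robust SDs per second; the mask is
  dilated by 1 s. The 20 s baseline is longer than the longest injected
  artifact, so shift plateaus are not absorbed into the baseline. On
  clean synthetic recordings the flagged fraction stays under 2%
  (asserted).
* **Correction**: each flagged run is replaced by a natural cubic spline
  bridged from 2 s of flanking clean data (a deterministic,
  Scholkmann-flavoured choice; the original toolbox offers several
  unspecified methods). Unflagged samples are returned bit-identical. A
  fully flagged participant loses all channels.
* **Beer–Lambert inversion**: per channel and sample, a 2×2 solve of
  `dOD_lambda = sum_c eps[c, lambda] dC_c d DPF_lambda`.
* **No band-pass filtering anywhere** — the downstream analysis is
  wavelet-based; a test compares out-of-band power before and after the
  chain (< 1% change on clean channels).

## 5. Wavelet coherence and IBS

The Morlet CWT (`omega0 = 6`, 12 voices per octave, periods 2–64 s by
default) is computed in the frequency domain on the zero-padded series.
Coherence uses the standard smoothing recipe: time smoothing by a
Gaussian with SD = scale/sqrt(2) (unit-DC frequency-domain transfer) and
scale smoothing by a 0.6-octave boxcar; these exact definitions are
mirrored by a literal loop-based DFT reference in the test suite, and
the two agree to 1e-6. The cone of influence is the wavelet's e-folding
time `sqrt(2) * scale`; by default, points outside the COI are excluded
from band and segment means (an included-COI policy is available), which
matters mostly for the 30 s rests at the record edges.

`IBS = mean band coherence (task1 + task2) - mean band coherence
(rest2)`, band 3.2–12.8 s, endpoints inclusive. The baseline is the rest
*between* the blocks per the source description ("the interval between
them"); a config option widens it to all three rests. Fisher-Z is
applied to the interval means and the difference taken in z-space
(`ibs_z`) for inference, while the raw coherence difference is reported
alongside. The only detrending before the CWT is per-segment mean
removal.

Numerical notes: coherence is clipped to [0, 1] and to `1 - 1e-10`
before `atanh`; smoothing denominators are floored at 1e-300; the
spectral matrices for a given series length are cached, since a cohort
run computes hundreds of channel pairs of identical length.

A calibration subtlety, measured by the acceptance suite: because the
30 s rest mean is noisier than the 300 s task mean and `atanh` is
convex, null `ibs_z` carries a small negative bias (about −0.004 here).
The one-tailed channel screening is therefore slightly conservative
under the null (~2.6% rejections at alpha = .05); the two-tailed
calibration sits at ~4.2%, and the BH-FDR false-positive rate over 22
channels stays at ~5%.

## 6. Granger causality

Time-domain bivariate only, matching the description of the directional
analysis: no conditional or spectral variants. Inputs are the task-block
HbO segments of the flagged channel, each block linearly detrended, with
lag rows never crossing a block boundary. `GC_{x->y} = ln(RSS_restricted
/ RSS_full)` with the standard nested-model F test at `(p, n - 2p - 1)`
degrees of freedom. The order is BIC-selected on the joint bivariate
model, capped at 20 lags (2 s at 10 Hz). Group level: one-sample t per
direction (one-tailed positive) and a two-tailed paired t between
directions — symmetric coupling must and does produce a null paired
test, mirroring the study's no-direction finding.

## 7. Group statistics

All tests are implemented from closed forms (with base R distribution
functions) so tails and effect sizes are explicit, and are cross-checked
in the tests against `t.test`, `aov`/`TukeyHSD`, `cor.test` and
`p.adjust` as independent oracles. Partial eta squared uses the one-way
identity `eta_p^2 = df1 F / (df1 F + df2)` — the published (F, df) pairs
recover the published values 0.442 / 0.370 / 0.444 / 0.232 to three
decimals. One reported statistic in the source (an IBS ANOVA with
F(2,39) and eta_p^2 = 0.235) is inconsistent with this identity and is
not reproduced. Classical equal-variance forms are the default (Welch
off), matching the reported degrees of freedom. The FDR step-up is a
literal Benjamini–Hochberg implementation fuzz-tested against
`p.adjust(..., "BH")`.

## 8. What a green run establishes

Everything here runs on synthetic dyads whose coupling is planted by the
forward model. The tests establish recovery of known ground truth —
planted channels pass FDR, planted lags give the right causal direction,
the behavioural decomposition emerges at the published cohort sizes —
with calibrated false-positive behaviour under the null. They do not
validate any claim about real couples, real optode physics (no photon
transport, channel positions are labels), or the interview-based
strategy classification, which is out of scope. Simulation-heavy checks
are scaled down from their nominal replicate counts to fit a small
compute budget; the proportions asserted are unchanged and each scaling
is noted where it happens.
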