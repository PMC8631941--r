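---
title: "Energy-landscape analysis of brain-state dynamics: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of brain-state dynamics: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statescape)
```

This vignette explains the models implemented in `statescape`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where the methodology left room.

## The pairwise maximum-entropy model

The substrate of the analysis is a time series of binary activity
patterns $V_t = (\sigma_1^t, \dots, \sigma_N^t)$, $\sigma_i = \pm 1$,
over $N = 7$ regions of interest (FEF, DLPFC, IFC, aSPL, pSPL, LOC, V5).
The pairwise maximum-entropy model assigns each of the $2^N$ patterns an
energy

$$E(V) = -\sum_i h_i \sigma_i - \tfrac12 \sum_{ij} J_{ij} \sigma_i \sigma_j,$$

and the probability $P(V) = e^{-E(V)} / \sum_l e^{-E(V_l)}$. It is the
maximum-entropy distribution consistent with the observed first and
second moments: $h_i$ is the basal tendency of region $i$ to be active
and $J_{ij}$ the coupling of regions $i$ and $j$. Energies are relative;
adding a constant changes nothing (`boltzmann_distribution()` normalises
on the log scale).

`fit_pairwise_mem()` performs plain gradient ascent on the
log-likelihood, whose gradients are exactly the moment gaps
$\langle\sigma_i\rangle - \langle\sigma_i\rangle_m$ and
$\langle\sigma_i\sigma_j\rangle - \langle\sigma_i\sigma_j\rangle_m$,
with model moments recomputed by exact enumeration every iteration. At
$N = 7$ the enumeration is 128 patterns, so no approximate inference is
needed or provided. Defaults: learning rate 0.1 with geometric halving
when the moment gap oscillates, tolerance $10^{-4}$ on the largest
moment gap, at most $10^5$ iterations. The likelihood is concave, so
the only failure mode is a too-large step, which the damping handles.

Fit quality is reported two ways: the Pearson correlation between model
probabilities and empirical pattern frequencies, and the KL accuracy
$(D_1 - D_2)/D_1$, where $D_1$ and $D_2$ are the divergences of the
empirical distribution from the best first-order (independent) model
and from the pairwise model. The first-order reference is closed-form:
$h_i = \mathrm{atanh}\langle\sigma_i\rangle$, clipped at
$\pm(1 - 10^{-9})$ because finite samples can produce means of exactly
$\pm 1$. Empirical-zero patterns contribute nothing to either divergence
($0\log 0 = 0$), and if $D_1 = 0$ (the data are exactly first-order) the
ratio is reported as 0 with a flag rather than as 0/0. One caveat worth
knowing: for *sampled* data from an independent model, $D_1$ and $D_2$
are both dominated by sampling noise and their ratio does not converge
to zero — the pairwise model absorbs the noise in the 21 pairwise
moments. The ratio is a useful summary only when $D_1$ is comfortably
above the sampling floor, as it is for genuinely interacting data.

## Landscape construction

Two patterns are adjacent iff they differ at exactly one region, making
the state space an $N$-cube. A local minimum lies strictly below all
$N$ neighbours. Basins are found by steepest descent: from every
pattern, repeatedly move to the lowest-energy neighbour while one is
lower. The saddle energy $E^*_{lm}$ of two minima is the lowest level
at which they are still connected when all patterns at or above the
level are removed — equivalently the min-over-paths of the max energy
along the path. `build_disconnectivity()` computes all saddles exactly
in one ascending-energy union–find sweep, and the disconnectivity tree
is the single-linkage dendrogram of $E^*$ (an ultrametric). Directional
barriers are $\mathrm{barrier}(l \to m) = E^*_{lm} - E(\min_l)$, so
$\mathrm{barrier}(l\to m) - \mathrm{barrier}(m\to l) =
E(\min_m) - E(\min_l)$ identically.

Coarse-graining absorbs a minimum $l$, with its basin, into a deeper
minimum $m$ whenever $\mathrm{barrier}(l \to m)$ is below a threshold
(default 1, in units of the dimensionless energy) and $E(\min_l) >
E(\min_m)$, repeating until no merge applies. The three surviving
basins with the most patterns are the major brain states, named by the
activity profile of their minima: F has the frontal trio active, V the
visual pair, Int the remaining one. Patterns of any other surviving
basin are labelled Other.

Numerical choices, all of which matter only on measure-zero ties but
must be fixed for determinism:

* steepest-descent ties go to the lowest pattern index;
* exact energy ties on a plateau raise an error rather than guess
  (the packaged templates carry a tiny $10^{-4}$ field jitter per ROI
  precisely so that no two patterns share an energy);
* qualifying merges are applied lowest-barrier-first and re-evaluated
  after each merge. The saddle matrix is a property of the landscape,
  not of the merge sequence; on the packaged landscapes randomised
  merge orders give the same final map, but on arbitrary landscapes a
  shallow minimum can have several qualifying absorbers, in which case
  the documented lowest-barrier-first order defines the output
  deterministically.

## Simulated dynamics

`metropolis_walk()` proposes one of the $N$ single-flip neighbours
uniformly and accepts with $\min(1, e^{E_i - E_j})$; a rejected
proposal repeats the pattern for one step, which is what gives dwelling
times their meaning. The stationary distribution is exactly the model's
Boltzmann distribution (detailed balance holds analytically, and the
tests verify both the identity and the empirical convergence).

Walk time is measured in steps. Where the smoothing and summary
operations need a clock, one step is equated to one sample at 300 Hz —
the offline analysis rate — so the 10 ms smoothing defaults translate
to 3-step windows. This convention is fixed and documented rather than
exposed, because mixing step- and second-based units silently is the
main hazard here; travel lengths are always reported in both.

State sequences are smoothed in two stages: appearance frequencies of
F/Int/V in a centred 10 ms window (Other counts in the denominator but
cannot win), Gaussian smoothing of the three frequency curves (FWHM
10 ms, $\sigma = \mathrm{FWHM}/2.355$), then a per-sample argmax with
ties resolved towards the earlier state in the fixed order F, Int, V.
Windows and kernels are truncated and renormalised at the sequence
edges. This removes the Other label and sub-window flicker.

A travel cycle starts when the smoothed sequence enters F and completes
at the first return to F after V has been visited; its length counts
every step in between, including back-and-forth moves. This is one of
several possible readings of an F–Int–V–Int–F excursion; it needs no
minimum-dwell parameter and, because direct F–V adjacency is
practically absent on the landscapes of interest, the passage through
Int is implied rather than enforced.

## The synthetic generator

`make_ground_truth()` ships a fixed parameter set (the `three_basin`
template) whose landscape has exactly three major states with the
qualitative structure described above. The construction is a
three-community model: frontal intra-couplings 0.4, visual
intra-coupling 0.9, frontal–visual couplings $-0.65$, a weakly coupled
parietal pair (intra 0.05, fields $-0.3$), and frontal/visual fields
solved in closed form so that the F and V minima sit 0.8 and 0.4 energy
units below the Int minimum. Int is realised as the all-inactive
pattern: a pairwise energy is quadratic, so it cannot penalise
co-activation of two communities without equally penalising their
co-deactivation, and every variant we explored with an *active*
intermediate pattern left a low-energy corridor of direct F–V
transitions well above the sub-percent level such landscapes should
show. With Int at the origin, the negative frontal and visual fields
price every mixed frontal+visual state several units above the saddles,
and the Int basin separates F from V almost completely.

Three further calibration notes, all fixed before the test suite was
frozen and none revisited since:

* the depth offsets (0.8, 0.4) keep each basin's Boltzmann mass close
  to its node fraction, which is what the basin-size vs
  appearance-frequency comparison measures;
* the coupling scale (cross-coupling 0.65) keeps the model identifiable
  from $10^5$ samples — much stronger couplings make the visual fields
  nearly redundant with the visual coupling and noticeably inflate the
  estimation error of $h$;
* a second template, `three_basin_het`, strengthens the FEF–IFC pair
  (0.85) at the cost of the links through DLPFC (0.30) and deepens the
  wells. Its frontal state survives virtual silencing of DLPFC via the
  neighbouring-vector rule, which the default template's does not (with
  uniform frontal couplings the frontal remnant sits only
  $\mathrm{depth}_F/3 \approx 0.27$ below its saddle to Int and is
  always absorbed). The variant exists for restriction studies; its
  deeper wells make it a poorer parameter-recovery target, which is why
  it is not the default.

`sample_binary_series()` draws i.i.d. patterns from the exact Boltzmann
distribution, optionally repeating the previous pattern with a
persistence probability — temporal autocorrelation with an unchanged
marginal. Real EEG state sequences are not first-order Markov in this
sense; the persistence knob exists to give the closed-loop simulator
state dwell times on the seconds scale of percepts, not to model
within-state dynamics.

`synthesize_eeg()` emits 28 channels (per ROI: one centre electrode and
three surrounding ones): the centre carries a 30–80 Hz carrier whose
envelope is `amp_high` = 1 while the ROI is active and `amp_low` = 0.25
while it is not, all channels share a common-mode component (removed by
average reference and by the Hjorth derivation), and broadband noise is
added at a requested variance ratio `snr` (the default 10 is a
calibration choice; no quantitative envelope SNR is available for real
gamma-band data). The carrier is random-phase band-limited noise whose
instantaneous modulus is equalised (alternating modulus normalisation
and band confinement for six rounds): a plain noise carrier has
Rayleigh fading that keeps per-sample recovery of the latent state
well below the package's round-trip target no matter the sensor noise, while the equalised carrier is still
spectrally broad — so FFT band extraction is exercised realistically —
but lets the Hilbert envelope track the imposed modulation. Carrier
scale is normalised by a fixed reference level
$\sqrt{(a_{high}^2 + a_{low}^2)/2}$, never by the realised variance, so
channel gain does not depend on how much time a realisation happens to
spend in each state. What the generator does **not** emulate: volume
conduction and realistic forward models, 1/f background spectra,
eye-movement or muscle artifacts, non-stationary amplitude drifts.
Passing tests on this generator show the pipeline's internal
consistency, not robustness to those nuisances.

Percept durations are linear in the travel length with Gaussian noise,
truncated at 0.1 s (durations are positive). Defaults: slope 0.016
s/step (typical travels of ~250 steps then give the ~4 s medians seen
in bistable perception) and noise SD 1.06 s, which at a documented
across-participant travel spread of SD 60 steps gives a population
correlation of 0.67.

## Offline preprocessing

The offline chain mirrors a standard EEG pipeline: average reference,
resampling to 300 Hz (zero-phase FIR decimation for integer factors,
polyphase resampling otherwise), zero-phase Butterworth band-pass
(broadband 1–80 Hz, then the analysis band 30–80 Hz), artifact-epoch
exclusion, per-channel Hilbert envelope, Hjorth derivation
$3c - (n_1 + n_2 + n_3)$ per ROI, binarisation at per-ROI thresholds.
Choices:

* epochs are 1 s and an epoch is excluded when its mean global field
  power exceeds the across-epoch mean by 5 SD; with fewer than three
  epochs there is no meaningful spread estimate and nothing is
  excluded;
* binarisation is strictly `>`, so a constant signal maps to inactive;
* thresholds default to each ROI's temporal mean of the supplied data.
  This assumes the data are long enough for occupancies to balance —
  a single run of a few dozen seconds with seconds-long states can
  place a mean threshold close to one of the amplitude levels and make
  the labels flicker. Sessions should pool runs before thresholding
  (the closed-loop evaluation below does), which is also how multi-run
  recordings are treated in practice;
* an optional first-difference pre-whitening of the envelopes before
  the Hjorth step exists behind a flag (default off): whether envelope
  autocorrelation should be removed at this point is ambiguous in the
  methodology this implements, so the step is explicit, not silent;
* independent component analysis is out of scope: the chain ingests
  raw or pre-cleaned matrices.

## The closed-loop simulator

`run_closed_loop()` is a deterministic simulator of the online system:
1000 ms windows at 2 kHz over the Hjorth signals; per window, FFT
masking to 30–80 Hz and analytic-signal envelope; 100 ms trimmed at
both edges; Yule–Walker AR(30) forward prediction of 280 ms (covering
$T = -100$ to $+180$ ms around the window end); binarisation against
control-run thresholds; labelling and smoothing (yielding $T = -95$ to
$+175$ ms); and the trigger rule: fire iff the target state occupies
more than 90 % of the decision span $T = 25..175$ ms — for
history-dependent conditions additionally the history state must
dominate $T = -95..25$ ms — and at least 9 s have passed since the last
honoured trigger. Honoured triggers are stamped at window end + 21 ms.
The stride of the sliding window is configurable (default 5 ms; the
hardware cadence of such systems is not standardised).

One deliberate deviation from the plainest reading of windowed
Yule–Walker: inside the loop the forecast reverts to the control-run
mean of each ROI (the same baseline the binarisation thresholds come
from) rather than to the current window's mean. When a window spans a
state transition, the window mean is contaminated by the pre-transition
level and a mean-reverting forecast is dragged back across the
threshold, producing confident false triggers; reverting to the session
baseline removes this failure mode without touching the AR
coefficients. The standalone `ar_forecast()` keeps the plain
window-mean behaviour as its default.

`evaluate_online()` scores the online stream against offline labels:
per-state agreement (with counts, so several runs pool at the sample
level, as a participant's runs would), trigger accuracy, and the
latency error (identically zero in simulation — the bookkeeping exists
for interface parity with hardware). Trigger accuracy asks whether the
target state holds for the majority of offline-labelled samples during
the 150 ms burst. Offline labels flicker on the 10 ms scale even in
clean synthetic data — as smoothed empirical state sequences do — so
requiring literally every burst sample would misclassify correctly
placed triggers; the all-sample variant is reported alongside as
`trigger_accuracy_strict`.

## Virtual stimulation

Complete inhibition of region $i$ is modelled as state-space
restriction: every pattern with $\sigma_i = +1$ is removed and the
landscape machinery reruns on the remaining $(N-1)$-cube with the same
$h$ and $J$ (surviving patterns keep their exact energies). A major
state whose minimum was removed is represented by the neighbouring
pattern differing only at the target region, and its label attaches to
the restricted coarse basin containing that neighbour; if two labels
land in one basin the landscape has genuinely lost a state and an error
is raised rather than a silent relabelling. The quantities of interest
are the four directional barrier changes (F→Int, Int→F, Int→V, V→Int)
and the change of the Int→F / Int→V barrier ratio. Graded inhibition
(e.g. shifting $h_i$) is deliberately not modelled; restriction is the
assumption under study. Basin sizes and barriers after restriction are
computed on the $2^{N-1}$ space itself, not re-embedded.

## Behavioural statistics

Median percept durations exclude mixed-percept events (durations are
long-tailed, hence the median); stimulation effects are proportional
changes (TMS − control)/control; predicted and observed quantities are
compared by MAPE. The effect-decay profile slides the analysis window
and reports the absolute Fisher $z$ of the across-participant
correlation between simulated barrier changes and measured neural
effects. Mediation is ordinary least squares with the product of
coefficients: $\alpha$ from $M \sim X$, $\beta$ and $\gamma'$ from
$Y \sim X + M$, $\gamma$ from $Y \sim X$, indirect effect
$\alpha\beta$ with a percentile bootstrap (default 5000 resamples) over
participants; $\gamma = \gamma' + \alpha\beta$ holds identically for
these linear fits. No covariates are used.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the
caller's RNG state. The test suite and the acceptance script use
exact enumeration at $N = 7$ (128 patterns), series of $10^5$ samples,
walks of $10^5$–$10^6$ steps, and closed-loop recordings of one to
three minutes at 2 kHz with a 25 ms stride — sizes at which every
quantity of interest is estimated to well within its tolerance on a
single CPU in minutes. Brute-force oracles (exhaustive path
enumeration, direct likelihood optimisation, explicit subgraph
connectivity) back the implementation at $N \le 4$ in the tests.

## Known limitations

* Exact enumeration limits the model to $N \le 20$ in principle and
  $N \sim 12$ in comfort; no pseudo-likelihood fallback is provided.
* The generator's latent process is a persistence-mixture, not a
  mechanistic model of percept dynamics; its EEG is a two-level
  amplitude modulation without physiological artifacts.
* The closed-loop simulator has no hardware latencies beyond the
  documented 21 ms bookkeeping; its latency error is zero by
  construction.
* On the default template, silencing a frontal region merges the
  frontal remnant into the intermediate state (the documented error is
  raised); landscapes whose states survive single-site silencing need
  heterogeneous couplings, as in the `three_basin_het` template.
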