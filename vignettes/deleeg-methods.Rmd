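---
title: "Methods: AR spectra, rPDC connectivity and the deleeg decision rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AR spectra, rPDC connectivity and the deleeg decision rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`deleeg` packages a complete quantitative-EEG screening analysis for
ICU delirium: autoregressive spectral estimation with split-band
normalization, the slow-to-fast power ratio (SFPR), renormalized
partial directed coherence (rPDC) with range-level group decisions, and
the accompanying group statistics. This vignette records the models,
the tunable parameters, the numerical choices, and the places where the
design was genuinely open — and what the synthetic validation does and
does not establish about real patient data.

## Signal model and preprocessing

Recordings are multichannel scalp EEG in microvolts at 10-20 positions
(default montage F3, F4, C3, C4, P3, P4, T7, T8 against a common-mode
reference at C2), digitized at a high rate (2048 Hz in the acquisition
chain we emulate), band-passed 0.16–52 Hz and down-sampled to 256 Hz.
`preprocess()` realizes the band-pass as a zero-phase (forward-backward)
Butterworth cascade — order 2 high-pass, order 4 low-pass, each applied
with `signal::filtfilt` so the effective orders double. Zero-phase
filtering matters here: phase distortion would masquerade as time-lagged
dependence between channels and bias the connectivity analysis. Because
the 52 Hz corner sits well below the 128 Hz output Nyquist frequency,
decimation after filtering is a plain integer stride. The filter family
and order are a design choice (the acquisition chain we emulate does not
specify one); any zero-phase realization with comparable corners gives
equivalent downstream results.

Artifact handling is annotation-driven, not automatic: spans of
movement or eye-opening are supplied with the recording (EDF/BDF plus a
`<stem>.annotations.tsv` sidecar), and `select_epochs()` places the
required number of non-overlapping 60 s epochs greedily, earliest
first, skipping any window that intersects an annotation. Greedy
earliest-first placement is deterministic, so a study re-run selects
identical data. Whether the three epochs should instead be spread
across the recording is unknowable from our reference setting; earliest
placement was chosen for reproducibility.

## AR spectra and band powers

Each channel of each epoch is fitted by `stats::ar.burg` at order
`sampling_rate / 4` — the order *rule* is stored, not the constant 64,
so a different rate re-derives the order. Burg's reflection-coefficient
recursion is the standard choice for high-order AR on short epochs; it
maximizes entropy subject to the empirical autocovariances and yields a
stable model by construction. Stability is still asserted, via the
reflection coefficients themselves: testing the characteristic
polynomial's roots is numerically meaningless at degree 64 (observed
spurious root moduli as low as 0.36 for models that are provably
stable), whereas |k_m| < 1 is exact.

The spectrum is evaluated on the fixed 0.5–45 Hz, 0.5 Hz grid
(90 points) shared by every estimate in a study. Band powers sum grid
points with half-open band edges [lo, hi) — Gamma closed at 45 Hz — so
the bands tile their normalization ranges with no double counting at 4,
8, 13 and 20 Hz. The Delta lower edge is 0.5 Hz, the grid start.
Relative powers use two denominators: Delta against the full 0.5–45 Hz
sum, Theta–Gamma against the 4–45 Hz sum. The rationale is robustness:
Delta dominates total energy and absorbs most movement-artifact power,
so isolating it keeps artifact residue from contaminating the
higher-band percentages; a built-in consequence (and test invariant) is
that Theta + Alpha + Beta + Gamma relative powers sum to exactly 100.

The SFPR divides summed power below 13 Hz (from the 0.5 Hz grid start)
by summed power from 13 to 45 Hz. A zero denominator is reported as
`Inf` rather than an error — a legitimate, if extreme, observation.

## VAR fitting and rPDC

Connectivity uses equation-wise least squares on `p` lagged copies of
the demeaned channels. The fit retains sigma_i^2 (X'X)^-1, the
per-equation coefficient covariance, because the renormalization is
built from it: for direction j → i at frequency f, the transformed
cross coefficients Z(f) = (Re, Im) of sum_k A_k[i,j] e^(-i omega k) are
standardized by their estimated covariance V-hat(f),
lambda(f) = Z' V-hat^-1 Z. Under zero true coupling lambda is
chi-square with 2 degrees of freedom, giving the analytic chance level
`qchisq(1 - alpha, 2)` (equivalently -2 log alpha). A near-singular
V-hat (possible on nearly deterministic channels) is
Tikhonov-regularized at 1e-12 of its trace with a warning rather than
failing the run.

The VAR order is genuinely open: the univariate order-64 rule is
infeasible for a dense 4-channel model on one 60 s epoch (1024 + free
parameters), and no principled value is dictated by the problem. The
default is 16 at 256 Hz — sub-Hz resonance structure is retained, and
62.5 ms of history is ample for scalp-level lag structure — and it is
configurable. Reduced montages are always *refit*: rPDC for a given
connection legitimately changes when channels enter or leave the model,
because the statistic conditions on the other modelled channels. The
package never sub-selects pairs from a larger model, and a test asserts
that 4-channel and 3-channel estimates differ.

## Decision rules: what "expected by chance" must mean

Two counting rules turn frequency-resolved statistics into verdicts,
and both needed calibration work beyond their naive reading.

**Detection against the chance level.** lambda(f) across the 90 grid
points is driven by only 2p estimated coefficients, so under the null
the exceedance indicators are strongly dependent: most fits show zero
exceedances, an occasional fit shows a long run of them. A binomial
critical count (independence assumption) is therefore badly
anticonservative — measured 15 % false directional detections on pure
white noise at nominal 5 %. `rpdc_detected()` instead simulates the
null count from the fitted model itself: coefficient vectors drawn from
N(0, R-hat) are pushed through the same lambda computation and the
detection threshold is the empirical (1 - alpha) count quantile (500
draws, fixed internal RNG substream, caller's random state untouched).
Measured false-detection rate: 0 of 60 white-noise fits; forward power
at the default benchmark (bivariate coupling, gain 0.4, lag 1, 60 s):
100 %.

**Group differences over ranges.** A frequency point "differs" when
each group's pooled mean (n = 15 epochs per group) lies outside the
other group's 95 % t confidence interval. The published wording of this
rule is one-sided; the implementation uses the symmetric conjunction so
the verdict cannot depend on group ordering. Two facts matter for
calibrating "the number of differing points expected at random". First,
the pointwise rule is *not* a 5 % test: its CI is scaled for a single
mean rather than a mean difference, and under a common normal null it
fires at ~11 % (computed deterministically in `pointwise_null_rate()`
by Gauss–Legendre quadrature over the two sampling distributions of the
group standard deviations — a quantity worth knowing even though the
default decision path no longer consumes it). Second, the
inter-frequency dependence described above applies to the flags too.
Measured on same-generator cohort pairs, a binomial critical count at
rate 0.05 flags 38 % of null comparisons and even the corrected rate
flags 21 %. The default calibration is therefore a permutation null:
pooled epochs are randomly relabelled between groups (200 permutations,
fixed substream) and the critical count is the (1 - alpha) quantile of
the permuted counts. One further device is needed because the count is
bounded: under strong effects both the true labelling and many
permuted ones saturate at all 90 points, so equal counts are broken
lexicographically by the mean standardized group separation over the
range (mapped into [0, 1) so a tie-break can never promote a smaller
count over a larger one). Measured calibration: 4.4 % of null pair
decisions flagged; attenuated-coupling cohorts recovered as
"all 6 reduced-montage pairs significant, delirium lower" in 20 of 20
cohort seeds. The binomial rule remains available
(`calibration = "binomial"`, any `point_rate`).

## Group statistics

The per-band ANOVA is the fully between-subjects two-way layout
(status x channel), which is what the error degrees of freedom of the
design it mirrors imply (80 observations - 16 cells = 64). Channels of
one subject are of course not independent; the p-values carry that
caveat and effect sizes are the primary readout at pilot scale.
Post-tests are classical Bonferroni comparisons using the pooled ANOVA
error term on the error df, with p multiplied by the channel count.
The SFPR comparison uses an exact Mann–Whitney test: U from midranks,
p by complete enumeration of all C(n1+n2, n1) group assignments
(bounded at n1 + n2 <= 20). At 5 vs 5 the smallest achievable
two-tailed p is 2/252 ≈ 0.0079 — worth remembering when reading the
uniform p-values complete separation produces.

## The synthetic cohort generator

`sim_config()` defines the study conditions: 5 subjects per group,
3 x 60 s epochs each, 8 channels at 256 Hz, 600 s recordings. Each
channel is a sum of five unit-variance AR(2) resonators (band centers
2, 6, 10, 16, 30 Hz; pole radius 0.9) scaled by per-band amplitudes
(control: Delta 8, Theta 2, Alpha 2.5, Beta 2, Gamma 1.2 microvolts),
plus a 1/f background (exponent 1, amplitude 1.5) and Poisson-placed
slow high-amplitude transients (0.3/min, 400 microvolts, 1 s) that are
exactly annotated. Directed coupling mixes the lagged *intrinsic*
signal of a source channel into a sink (default: all 12 ordered pairs
among F3, C3, P3, T7, gain 0.3, lags 2–5 samples); feed-forward mixing
is unconditionally stable while still creating true Granger-causal
structure, and a spectral-radius check on the gain adjacency rejects
configurations whose implied feedback would not be. The delirium
condition multiplies Delta/Theta/Alpha amplitudes by 2, Beta/Gamma by
0.4, and coupling gains by 0.3 — the direction and rough size of the
group differences the pipeline is designed to detect, set large to
mirror the clear separation the reference setting reports at n = 5.

Two defaults deserve their rationale spelled out. The pole radius
trades realism against identifiability: at radius 0.95 the composite
channel (a sum of AR processes plus 1/f noise) has such long AR(∞)
memory that a finite-order VAR truncation leaves genuine residual
reverse-direction information, which rPDC — working as designed —
flags in a few percent of seeds; radius 0.9 keeps that leak below
detectability while band peaks remain plausibly wide. The fast-band
amplitudes (Beta 2, Gamma 1.2) keep Beta/Gamma from being dominated by
slow-resonator tail leakage, at the cost of a control Delta share of
~60 % of total energy rather than the ~80 % seen clinically. A related
honest limitation: because the delirium preset scales Delta, Theta and
Alpha *uniformly*, the Delta share of total power moves only through
the shrinking fast bands, so the Delta status effect is the weakest and
most seed-dependent of the five (its F ranges from ~0 to ~10 across
cohort seeds, where Theta's exceeds 1000).

What passing tests on this generator shows: the estimators recover
known spectra, peak locations, coupling directions and group effect
directions at realistic epoch lengths, and the decision rules hold
their nominal error rates under the generator's null. What it cannot
show: robustness to volume conduction and shared-reference effects
(channels are generated independently up to the explicit coupling),
non-stationarity within epochs, real artifact morphology, medication
effects, or subject-level heterogeneity (simulated subjects are
exchangeable draws from one condition distribution). Conclusions about
real patients rest on the analysis design, not on these simulations.

## Numerical and reproducibility notes

* All randomness in the generator derives from explicit seeds;
  per-subject seeds are drawn deterministically from the master seed.
  Identical config + seed reproduces recordings bit for bit.
* Internal Monte-Carlo calibrations (detection null, permutation null)
  use fixed private RNG substreams and restore the caller's
  `.Random.seed`, so they perturb nothing and are themselves
  reproducible.
* EDF quantizes to 16 bits over each channel's actual range (BDF: 24
  bits); round-trip error is below half a quantization step and the
  test suite asserts exactly that bound.
* Degenerate inputs fail loudly and specifically: constant signals
  (zero-variance AR fit), duplicated channels (rank-deficient VAR),
  unbalanced ANOVA tables, epochs that cannot avoid artifacts. The one
  deliberate non-error is SFPR = Inf for an empty fast band.
* Monte-Carlo test sizes (20–40 seeds for estimator properties, 200
  epochs/replicates for calibration checks, one full cohort for the
  end-to-end pattern) were chosen so the whole suite exercises every
  claim at meaningful resolution while remaining routine to run; the
  acceptance script's single default study takes well under a minute.
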