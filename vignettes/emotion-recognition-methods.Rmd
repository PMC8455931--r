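---
title: "Methods: TQWT sub-band features and grey-wolf selection for five-class EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TQWT sub-band features and grey-wolf selection for five-class EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it implements,
the choices made where the design was genuinely open, and what the test
suite does and does not demonstrate.

## The recognition problem

Emotional state is modelled on the valence–arousal plane. Each trial of a
DEAP-layout recording (40 trials × 32 EEG channels × 8,064 samples at
128 Hz, i.e. 63 s) carries 1–9 self-assessment ratings. Ratings are
discretized into three levels by the integer partition 1–3 / 4–6 / 7–9
(realized on the continuous scale as [1,4), [4,7), [7,9]) and the level
pair maps to five classes: (+1,+1) happy, (+1,−1) anger, (−1,−1) sad,
(−1,+1) relax, and any zero level neutral. The anger/relax quadrants
follow the published scheme verbatim even though the conventional
circumplex places them the other way around; because the matter is
genuinely ambiguous, `map_levels_to_emotion(..., swap_quadrants = TRUE)`
exchanges the two. The three-bin partition is taken as the authoritative
level rule; a single "threshold 3" variant would be a different
discretization and is not implemented.

## Preprocessing

The chain mirrors the DEAP preprocessed release: downsampling to 128 Hz
(`resample_signal`, polyphase anti-aliased via the `signal` package),
a 4–45 Hz band-pass, and the common average reference. The band-pass is
a two-pass (forward–backward) Butterworth of order 4 per pass
(`signal::filtfilt`), chosen because zero-phase filtering leaves the
time-domain feature values free of group-delay distortion; no particular
filter family is dictated by the method itself. Ocular-artifact removal
is out of scope: the reader assumes artifact-cleaned input, as in the
preprocessed DEAP release.

## The tunable Q-factor wavelet transform

TQWT is an oversampled two-channel filter bank iterated `J` times on its
low-pass branch, parameterized by the quality factor `Q` (center
frequency over bandwidth), the redundancy `r`, and the depth `J`. The
scaling factors are `h = 2/(Q+1)` and `l = 1 - h/r`; `l + h > 1`
whenever `r > 1`, which is what makes the bank oversampled. A `J`-stage
analysis yields `J + 1` sub-bands: the `J` high-pass outputs (highest
frequency first) plus the final low-pass output. Only the `J`-level
product forms of the filter responses are fixed by the method; the
single-stage prototype is the standard construction from the transform's
original reference — piecewise-constant pass/stop bands joined by the
two-vanishing-moment Daubechies transition
`theta(w) = 0.5 (1 + cos w) sqrt(2 - cos w)`, whose power complement
satisfies `theta(w)^2 + theta_c(w)^2 = 1` so the two channels form a
tight frame.

Numerical realization:

* DFT domain, unitary normalization throughout, so Parseval checks are
  direct equalities.
* Even-length bookkeeping per stage: `N0 = 2 round(l N / 2)` low-pass
  and `N1 = 2 round(h N / 2)` high-pass samples; the transition band has
  `T = (N0 + N1 - N)/2 - 1` bins per side, which by construction ends
  exactly at the sub-band Nyquist bin.
* Because every DFT bin's energy is split with weights whose squares sum
  to one, the transform is an *exact* tight frame: measured
  reconstruction and energy errors are ~1e−14 relative, asserted at
  1e−8 in the tests to leave FFT round-off headroom at other lengths.
* Odd-length inputs are zero-padded by one sample and the pad is
  stripped on reconstruction.
* `max_stages` counts feasible stages structurally (each stage must keep
  a positive transition band, an even shrinking low-pass length ≥ 4 and
  a high-pass length ≥ 2); decomposition at a deeper `J` raises an error
  naming the bound.
* The total coefficient count approaches `r·N` only as `J` grows (the
  geometric series of high-pass lengths); at `J = 4` it is ≈ 2N. The
  redundancy parameter describes the limit, not any finite depth.

The working parameter set is `Q = 3, r = 3, J = 4` (five sub-bands);
the per-subject sweep explores `Q` in 1..5, `J` in 1..6 with `r = 3`.

## Features

Five scalars per sub-band per channel, so one subject's matrix per
feature type is 40 × 160 with a complete (sub-band, channel) column
index. Conventions that required a decision:

* **Sample entropy** `-ln(A/B)`: canonical self-match-excluded template
  counting with Chebyshev distance, `m = 2`, `u = 0.2 std` — the
  intermediate normalizations cancel in the ratio, so raw pair counts
  are used. `u` is computed per sub-band sequence (features are defined
  on sub-band signals), with the population (divisor-`N`) standard
  deviation, kept consistent with the variance convention of the Hjorth
  parameters. The C++ kernel bins templates by their first two embedding
  coordinates on a grid of cell size `u` and compares only neighbouring
  cells; an O(N²) brute-force enumeration in R is kept in the test suite
  as the independent oracle. `A = 0` returns `Inf` with a warning,
  `B = 0` is an error, constant signals return 0 with a warning.
* **Second-order difference mean** is implemented exactly as printed — a
  *signed* mean, which telescopes to
  `(x(N) + x(N-1) - x(2) - x(1))/(N-2)`. Much of the literature uses the
  mean absolute lag-2 difference; `absolute = TRUE` opts into that
  variant. The signed form carries little class information on symmetric
  signals (visible in the synthetic benchmarks), but fidelity to the
  printed definition wins.
* **Hjorth mobility/complexity** use the first discrete difference as
  the derivative with no sampling-rate scaling (the standard discrete
  convention; units cancel in complexity).
* Degenerate cells (flat sub-bands, infinite entropy) are imputed to 0
  and counted in a message rather than aborting a subject.

Fusion layouts: per-subject sub-band-fused (40 × 160), cohort-pooled
per-sub-band (subjects·40 × 32), and fully fused (subjects·40 × 160),
with row/column provenance carried as attributes.

## BGWO2 feature selection

The published recipe fixes only the binarization: a donor-bit average
squashed through the steep sigmoid `S(a) = 1/(1 + exp(-10(a - 0.5)))`
and thresholded against a uniform draw per bit. The surrounding
mechanics follow the original grey-wolf optimizer: control scalar `a`
decaying linearly 2 → 0, per-dimension coefficients `A = 2 a rand - a`
and `C = 2 rand`, distance `D = |C X_leader - X|`, and a continuous
candidate `X_leader - A D` computed on the binary positions read as 0/1
reals. Each of the three leader candidates is squashed and stochastically
binarized *independently* before the donor average — the closest literal
reading of "binary steps". Leaders are maintained elitist (best three
positions ever seen, earliest evaluation winning ties), which makes the
best-so-far fitness trace non-increasing by construction.

The wrapper objective is nowhere stated in the source method, so the
package adopts the convention
`w · CV-error + (1 - w) · |mask|/d` with `w = 0.99`, stratified 6-fold
SVM error on the selected columns, and the same folds reused for every
candidate mask (comparability across masks, full determinism from the
seed). Empty masks are repaired to one random bit. Pack size 8 and
`T = 70` iterations are defaults in line with the binary-GWO literature;
all of it is configurable. Published reduction ranges (e.g. 160 → 57–92
columns) are treated as descriptive of one dataset, not contractual: the
package's contract is contraction without material accuracy loss.

## Classifier and indices

One-vs-rest RBF SVM (`e1071` binary machines with explicit
decision-value orientation), cost 1, bandwidth `1/d` on z-scored
features; standardization is fitted on each training fold only. Folds
are stratified by a least-loaded assignment that keeps both per-class
and global fold sizes within one member; classes smaller than the fold
count trigger a warning and best-effort stratification. Per-fold
confusion matrices are aggregated before computing accuracy
(100 · trace/total), macro one-vs-rest sensitivity and specificity
(zero-support classes excluded with a warning), and kappa.

**Kappa here is an accuracy normalization**, `(Acc − 1/k)/(1 − 1/k)`
with the uniform chance rate `p_e = 1/k` (0.2 for five classes). It is
*not* Cohen's marginal-product kappa: it depends only on accuracy and
the class count. This is deliberate — it is the convention used by the
benchmark this package validates against, and it reproduces every
published cross-method conversion to within printed rounding (checked in
the acceptance suite).

## The synthetic cohort generator

`generate_cohort` emulates the DEAP shapes exactly (40 × 32 × 8,064 at
128 Hz — the `duration · fs = 8064` invariant is enforced) with:

* a 1/f background (frequency-domain synthesis, randomized phases,
  default exponent 1, sd 8 µV above 1 Hz),
* band-limited Gaussian oscillations in theta 4–8, alpha 8–13, beta
  13–30 and gamma 30–45 Hz with base sds 4 / 5 / 4 / 3 µV — chosen once
  as realistic relative scalp-EEG magnitudes,
* class-conditioned band-power modulation `1 + effect_size · template`
  (happy: beta+gamma up; anger: beta up, alpha down; sad: theta up;
  relax: alpha up; neutral: baseline), with mild per-channel log-normal
  jitter. The templates are identifiability fixtures, not scientific
  claims about emotion physiology.
* ratings at the level-bin centers 2 / 5 / 8, so the label maps recover
  the latent class exactly by construction.

What it does *not* emulate: volume conduction and channel covariance
structure, artifacts, non-stationarity, inter-subject variability of
spectra, or any genuine emotion physiology. Consequently, passing
synthetic benchmarks demonstrates that the pipeline's machinery is
correct and that it can detect class-conditioned spectral structure of a
known size — it says nothing about accuracy on real EEG, where effect
sizes are far smaller and structured differently. At `effect_size = 0`
the generator is an exact null: classes differ in nothing, and the
pipeline must sit at the 20% chance rate.

`planted_feature_matrix` is the selection fixture: column `j` is shifted
by `effect` standard deviations for class `((j−1) mod 5) + 1`, noise
columns are standard Gaussian, so the informative set is known and
recovery is measurable.

## Problem sizes used in the checks

The validation suite runs entirely at desk scale, by the package's own
choice of sizes: full DEAP-shaped trials (8,064 samples, 32 channels, 40
trials — never shortened), cohorts of 1–2 synthetic subjects for
end-to-end checks, a 10-seed single-subject null for the chance-rate
check, and a 150 × 32 planted fixture with a pack of 8 and 30 iterations
for selection-recovery (majority over 5 seeds). Published-table
arithmetic (column means, per-sub-band accuracy increases, kappa
conversions across class counts) is recomputed from the shipped
reference tables and compared at printed precision. Wall-clock timings
are recorded in pipeline reports as diagnostics but never asserted.

## Known limitations

* The signed second-difference feature is nearly uninformative on
  symmetric broadband signals; it is kept signed for fidelity, with the
  absolute variant one flag away.
* The BGWO objective, SVM kernel and hyperparameters are conventions
  (the source method treats the classifier as a commodity); results on
  real data will be sensitive to them.
* Per-subject runs cross-validate only 40 trials with up to five
  imbalanced classes under 6-fold CV; stratification is best-effort and
  warned about, and accuracy estimates at that size carry large variance.
* The DFT-domain transform is periodic; near shift-invariance of
  sub-band energies holds exactly for circular shifts and approximately
  (tested < 1%) for windowed content under small linear shifts.
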