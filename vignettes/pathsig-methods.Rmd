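---
title: "Signature and lead-matrix features for multichannel epochs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature and lead-matrix features for multichannel epochs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the method it implements: the
model and its assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical and design choices made
where the method leaves them open.

## 1. The signature of a sampled multichannel path

A d-channel epoch is interpreted as the piecewise-linear path through its
samples. The truncated signature collects, per level $m \le k$, all
iterated integrals
$$S^{(i_1,\dots,i_m)}(X) \;=\; \int_{a<t_1<\dots<t_m<b}
  dX^{i_1}_{t_1}\cdots dX^{i_m}_{t_m},$$
giving a feature vector of length $\sum_{m\le k} d^m$ that does not depend
on the number of samples. Two invariances drive the application to
biosignals: adding a constant vector to all samples changes nothing
(increments are shift-free), and any monotone reparametrization of time
that preserves the node sequence changes nothing (the integrals only see
the trace of the path). Both are exercised as package invariants.

**Interpolation convention.** Samples define a piecewise-linear path and
the signature is computed *exactly* for that interpolant: a straight
segment with displacement $\Delta$ has the closed form
$S_m = \Delta^{\otimes m}/m!$, and segments combine with Chen's identity
$S(X*Y) = S(X)\otimes S(Y)$. This is the standard convention of signature
computation software; no smoothing or basepoint/time augmentation is
applied. The same identity yields the streaming update: the state of an
online computation is the running truncated signature plus the last sample,
with an $O(d^k)$ cost per new sample.

**Tensor storage and flattening.** Dense vectors of length $d^m$ per level,
flattened in row-major multi-index order (first index most significant) and
named `s<level>_<i1>_<i2>_...`. Feature vectors for classification default
to the *cumulative* set of levels 1..k; whether a "level-k" study means
level k alone or levels up to k is genuinely ambiguous in practice, so both
are supported (`feature_spec(..., cumulative = FALSE)`), with cumulative as
the default since it is what a truncation of the full signature gives.

**The quadrature oracle.** `quadrature_oracle()` integrates the definition
directly — resample on a fine uniform grid, then nested midpoint-rule sums
over the ordered simplex — sharing no code with the tensor-algebra route.
It is second-order accurate: at 4000 steps the relative disagreement on
smooth three-channel paths is a few parts in $10^6$, comfortably below the
$10^{-4}$ bar the tests use. It is restricted to $k \le 3$ because its cost
grows as $d^k \times$ steps.

## 2. Lead matrix and cyclicity analysis

The lead matrix is the antisymmetric part of level 2,
$L = \tfrac12(S_2 - S_2^\top)$; entry $(i,j)$ is the signed area of the
path projected on channels $(i,j)$, and $L_{ij}>0$ is read as channel i
leading channel j. For a system of phase-lagged unit sines
$X^i_t = \sin(t - \alpha_i)$ over $T$ that is a whole number of periods,
$L$ has the closed form
$$L \;=\; \tfrac{T}{2}\,(y x^\top - x y^\top),\qquad
  L_{ij} = \tfrac{T}{2}\,\sin(\alpha_j - \alpha_i),$$
with $x=\sin(\alpha)$, $y=\cos(\alpha)$ — rank 2, with the cyclic order of
the $\alpha_i$ recoverable from the phases of the dominant eigenvector's
components.

**Sign convention.** Direct evaluation of the signed-area integral
$\tfrac12\int (X^i \dot X^j - \dot X^i X^j)\,dt$ for these sines gives
$\sin(\alpha_j - \alpha_i)$; a form with the opposite sign,
$\sin(\alpha_i-\alpha_j)$, also circulates in the literature. The package
takes the antisymmetrized $S_2$ as *defining* L everywhere, and
`analytic_sine_lead_matrix()` implements the sign that matches it (verified
entrywise on sampled closed sine paths). With this convention the channel
with the smaller offset — the one that peaks first — leads, which is the
natural reading.

**Exactness of phase recovery.** A point that matters for testing: the
eigenvector component phases equal the generating offsets *exactly* only
when the offsets are balanced, $\sum_i e^{2i\alpha_i} = 0$ (e.g. uniformly
spread). For generic offsets the eigenvector is a complex mixture of
$x$ and $y$ and only the cyclic *order* is guaranteed. The package's exact
assertions therefore use balanced offsets; order recovery with generic
offsets is tested separately. A useful discretization fact: on a uniform
closed sampling grid the polygonal signed areas are *exactly* proportional
to $\sin(\alpha_j-\alpha_i)$ (the discretization enters as a common factor
$\frac{n\sin h}{2}$, $h$ the angular step), so rank-2 structure and phase
recovery hold to machine precision, not merely to $O(h^2)$.

**Conventions in `cyclic_order()`.** Conjugate pairs are sorted by
descending eigenvalue modulus; within a pair the positive-imaginary member
is reported; equal-modulus ties across pairs are broken by the channel
index of the largest eigenvector component; phases are rotated so the
largest-modulus component sits at phase 0. A global orientation flip
(conjugation) is inherent, so downstream comparisons must allow one
rotation and one flip — `align_phases()` does exactly that. A conjugate
pair counts as a detected oscillating set when its modulus exceeds a
configurable fraction (default 0.1) of the largest; exact tests use the
machine-scale threshold implicitly via rank checks instead.

## 3. SPD features and the affine-invariant geometry

$A = -L^2 = L^\top L$ is positive semidefinite
($v^\top A v = \|Lv\|^2$); adding $\varepsilon I$ makes it SPD. The
default $\varepsilon = 0.001$ is deliberately small: it is a floor, not a
tuning knob, and the spectrum of the feature is the squared singular values
of L shifted by $\varepsilon$ (asserted as an invariant). Covariance
features use the unbiased ($n-1$) estimator with mean removal, with
optional shrinkage toward the scaled identity for short windows.

The classifier layer works on the SPD manifold under the affine-invariant
metric only: distances
$\delta(A,B) = \|\log(A^{-1/2}BA^{-1/2})\|_F$, Karcher means, and
tangent-space projection at a reference (vectorized with $\sqrt2$-weighted
off-diagonals so Euclidean tangent norms equal Riemannian distances at the
reference). `mdm()` is nearest-class-mean in this metric; distance ties go
to the earliest factor level. `tangent_classifier()` projects at the
Karcher mean of the training features (identity optional) and fits a
configurable linear rule — ridge-regularized logistic regression by
default, chosen because the tangent dimension $d(d+1)/2$ routinely exceeds
the trial count and a convex, deterministic fit keeps reports reproducible;
linear SVM and LDA are available where the sample size supports them.

**Numerical choices.** All matrix functions go through symmetric
eigendecomposition with eigenvalues clipped at $10^{-12}$, guarding
round-off on $\varepsilon$-regularized inputs. The Karcher mean iterates
the standard tangent-space fixed point from the arithmetic-mean start, with
backtracking: a step is accepted only if the gradient norm does not
increase, halving the trial step otherwise and letting it recover
geometrically (cap 1). Tolerance is $10^{-8}$ on the tangent-mean norm with
a 200-iteration cap: lead-SPD features can have eigenvalue spreads of
$10^6$ and more, and on such clouds the plain unit-step iteration
oscillates while the stable step spends dozens of iterations in a slowly
contracting transient before the fast phase — 50 iterations, a common
default, stops short there. Non-convergence is a warning carrying the last
iterate and diagnostics, never a hard failure: a slightly unconverged mean
is still a serviceable tangent reference, and the warning propagates
through the classifier so a user sees it.

## 4. What the synthetic generators emulate

`gen_lagged_sines()` / `gen_multiset_sines()` reproduce the analytic
setting above (closed sampling grids when duration × frequency is an
integer, so the closed forms are exact) and are the oracles for the
cyclicity layer.

`gen_mi_epochs()` emulates two-class motor-imagery-like epochs at the
geometry of a standard 22-channel, 250 Hz, 3 s recording, 100 trials per
class. Each trial is a sum of band-limited oscillatory components — each
with a per-class per-channel phase map (the lead-lag structure) and a
per-class amplitude (the desynchronization-like modulation) — plus white
noise (sd 2) and a 1/f-like background (sd 1), with a fresh uniform global
phase per component and trial and per-channel phase jitter (sd 0.05 rad).

The three presets encode the study conditions:

- **lead-lag**: components at 9 and 27 Hz, equal amplitudes; one tight
  phase map (offsets within 0.6 rad — a weakly sequenced set with small
  pairwise signed areas) and one balanced wide map, *swapped between the
  frequencies* across classes. The covariance expectation is then
  identical for both classes (the cosine terms sum over both maps either
  way), while the lead matrix weights each component by its frequency (more
  cycles, more area), so $L^\top L$ differs between classes — and differs
  in its log-spectrum, which is what the affine-invariant tangent map
  preserves well. This construction was chosen after observing that two
  simpler ones are *invisible* to the method: a pure lag reversal flips L
  globally and $-L^2$ cannot see it, and for a single narrowband source
  covariance ($\propto \cos\Delta\phi$) and lead-SPD carry the same
  information. Neither is a defect of the implementation; both are
  structural properties of the feature, worth knowing when designing real
  studies.
- **amplitude**: phase maps redrawn uniformly at random every trial (same
  distribution in both classes — no stable lead-lag structure at all), and
  the 9 Hz component attenuated to 60% in class 2. Band power carries the
  class, lead matrices do not.
- **null**: identical class configurations; classes are exchangeable by
  construction, so any feature/classifier pair should score inside the
  binomial band of chance.

The background level is part of the model, not a nuisance: EEG is
broadband, and the in-band noise floor raises the small eigenvalues of
$L^\top L$, which *stabilizes* their logarithms; with an implausibly clean
background the tangent coordinates of the noise directions fluctuate more,
not less.

What the generator does **not** emulate: volume conduction and realistic
forward-modeled topographies, time-resolved desynchronization curves (the
amplitude effect is a static per-trial factor), ocular/muscle artifacts,
nonstationarity within a trial, and session effects. Passing the package's
tests therefore shows that the machinery recovers the structures it targets
under controlled conditions — it does not predict accuracy on real
recordings, where published motor-imagery benchmarks sit far lower.

`gen_multi_subject()` adds subject-level nuisance (log-normal gain, a
Cayley-transform channel rotation near identity, a subject-wide phase
shift) to make leave-one-subject-out validation meaningful on synthetic
data.

## 5. Pipeline conventions

- **Filtering**: order-4 Butterworth band-pass (8–30 Hz default), applied
  forward and backward (`signal::filtfilt`) so the phase response is zero —
  essential here, since a phase-distorting filter would corrupt the very
  lead-lag structure being measured. Epochs are filtered before feature
  extraction; "raw" features in the vector study mean filtered,
  unnormalized channels.
- **Cross-validation**: stratified k-fold (default 10) with fold assignment
  a deterministic function of seed and labels, or leave-one-subject-out
  keyed on subject ids; classifier training randomness is re-seeded per
  fold. Reports (per-unit accuracies, mean, sd) are byte-reproducible given
  config + seed, which the CLI layer turns into byte-identical output
  files.
- **Responder split**: subjects grouped by reference-method accuracy
  against a threshold (default 0.5, chance), alternative-vs-reference
  compared within groups by paired t-tests with Bonferroni correction over
  the two groups ($\alpha$ nominally 0.05); degenerate groups (empty, or
  zero-variance differences) yield NA p-values rather than errors.
- **I/O**: the canonical on-disk form is a long CSV (trial, channel,
  sample_index, value) with a JSON sidecar for labels, channel ids, rate
  and subjects — lossless round-trip. EDF export/import (16-bit, one data
  record per trial) is provided for interchange and round-trips within
  quantization; GDF import is not implemented.

## 6. Problem sizes used by the test and acceptance runs

Signature oracles run on ~1.1k-sample 3-channel smooth paths with a
4000-step quadrature grid; sine-system checks use $10^4$ samples over two
periods; Riemannian property checks use 200 random SPD pairs at
$d \in \{2, 8, 22\}$; the classification studies run the full
22-channel × 750-sample × 200-trial condition end to end; scaled-down
variants (6–8 channels, 1.5 s) exercise the same code paths in the unit
tests. These sizes were chosen so the entire suite completes in a few
minutes on a single CPU while still running every study at its stated
geometry.

## 7. Known limitations

- Signature levels above 4 are unsupported in the pipeline layer (feature
  lengths explode as $d^k$); the core functions accept any level but cost
  $O(n\,d^k)$ per path.
- The Karcher mean on extremely spread SPD clouds (short, low-channel
  trials) can exhaust its iteration cap; it warns and returns the last
  iterate. If this occurs in a study, lengthening trials or raising
  $\varepsilon$ is the principled remedy.
- `-L^2` is blind to a global sign flip of the lead matrix: two conditions
  that differ only by reversing *every* lead relationship produce identical
  features. The raw lead matrix (or its eigenvectors) must be inspected
  when that distinction matters.
- The CSV epoch dialect stores one value per row and is meant for
  moderate epoch sets, not continuous recordings.
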