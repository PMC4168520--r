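---
title: "Methods: multiple kernel learning for EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple kernel learning for EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromkl)
```

## The model

`neuromkl` classifies multichannel EEG with a soft-margin SVM whose kernel
is a learned convex combination of a bank of basis kernels,

$$K(x, x') = \sum_{m=1}^{M} d_m K_m(x, x'), \qquad
  \sum_m d_m = 1,\ d_m \ge 0,$$

trained by the reduced-gradient scheme usually called SimpleMKL.  For
fixed weights $d$ the problem is an ordinary SVM dual,

$$J(d) = \max_{\alpha}\ \sum_i \alpha_i - \tfrac12 \sum_{i,j}
  \alpha_i \alpha_j y_i y_j \sum_m d_m K_m(x_i, x_j),
  \qquad 0 \le \alpha_i \le C,\ \textstyle\sum_i \alpha_i y_i = 0,$$

and $J$ is differentiable in $d$ with
$\partial J / \partial d_m = -\tfrac12 \alpha^\top Y K_m Y \alpha$ at the
optimal $\alpha$.  The solver alternates an exact inner dual solve with a
step $d \leftarrow d + \gamma D$ along the reduced-gradient direction
projected on the simplex, and terminates when the duality gap
$\max_m \alpha^\top Y K_m Y \alpha - \alpha^\top Y K(d) Y \alpha$ falls
below tolerance.  The decision function is the usual support-vector
expansion $f(x) = \operatorname{sgn}(\sum_{sv} \alpha_i y_i K(x, x_i) + b)$.
Multiclass problems use one-versus-rest with the largest decision score
winning (ties to the earlier class label).

The default bank is three polynomial kernels (degrees 1–3) and ten
Gaussian RBF kernels (widths 0.5, 1, 2, 5, 7, 10, 12, 15, 17, 20) —
thirteen kernels.  A sigmoid kernel is implemented for completeness but is
not in the default bank: it is not positive semidefinite in general and is
not part of the reference configuration.

### Numerical choices in the solver

* **Inner solver.**  Sequential minimal optimization with second-order
  working-set selection, warm-started across outer iterations.  The
  contract is KKT satisfaction to a tolerance (default `1e-6`), not a
  named algorithm.
* **Line search.**  The largest simplex-feasible step `gamma_max` is tried
  first (this is what drives weights exactly to zero at the boundary),
  backtracking by halving up to 20 times until the objective decreases,
  followed by a short golden-section polish.  Accepted steps therefore
  never increase $J$, and the recorded objective path is non-increasing.
* **Tie-break.**  The reference weight $\mu$ is the largest component of
  $d$, smallest index on ties.  Weights below `1e-8` are snapped to zero
  and the vector renormalized, which keeps the zero-weight branch of the
  direction formula well defined.
* **Termination.**  `C` and the gap tolerance are not dictated by the
  method itself; defaults are `C = 100` and a gap of 1% relative to the
  combined quadratic form (absolute fallback `1e-4`), both exposed in
  `mkl_settings()`.  Initialization is uniform weights.
* **Reduced-gradient direction at the boundary.**  For a zero weight with
  a favourable reduced gradient the direction re-opens that coordinate
  (the balancing component $D_\mu$ absorbs the sum), so the iterate can
  re-enter a kernel it previously dropped; with an unfavourable reduced
  gradient the coordinate stays blocked at zero.

The solver is validated against an exhaustive simplex grid search (step
0.01, locally refined around its argmin) with the same exact inner QP on
small instances: the attained
objectives agree to `1e-3`, and a one-kernel bank reproduces a plain SVM's
decision values to `1e-6`.

## Feature path 1: wavelet-packet entropy

Each channel of each trial is decomposed with a full wavelet-packet tree
(db4, 4 levels by default) implemented as a periodized orthogonal filter
bank; signals are zero-padded to a dyadic-compatible length and the
padding removed after reconstruction, so the round trip is exact and the
coefficient energy equals the signal energy.  Nodes are indexed in natural
frequency order (the low/high children of a node swap when the parent
occupies an odd frequency slot, because decimating a highpass branch
mirrors the spectrum).

Two band maps are provided:

* `scheme = "literal"` (default): level-4 nodes 0, 1, 2 for delta, theta and
  alpha, and node 3 plus level-2 node 1 for beta.  At 250 Hz a level-4
  node spans about 7.8 Hz, so these nodes do **not** coincide with the
  nominal 0–4 / 4–8 / 8–12 / 12–32 Hz edges; the map is retained verbatim
  as the reference configuration rather than silently corrected.
* `scheme = "edges"`: level-5 nodes grouped by the nominal band edges
  (each node assigned to the band containing its centre frequency).  This
  is the map used by the band-selectivity checks — a 6 Hz tone belongs to
  theta only under this map.

The per-band feature is a Shannon entropy of the band component.  Two
modes exist and the difference matters:

* **normalized** (default): squared samples are converted to a
  probability distribution, $SE = -\sum_t p_t \ln p_t$.  This is the
  standard wavelet-entropy form, scale-invariant and bounded by $\ln T$.
  Being scale-invariant, it measures the *shape* of the component and is
  blind to a pure power change.
* **literal**: $SE = -\sum_t f_t^2 \ln f_t^2$ with $0 \ln 0 = 0$.  This
  form scales with component energy and is therefore the appropriate
  choice when the discriminating signal is band *power* — the synthetic
  classification study (classes differing only in alpha power) uses it
  for exactly that reason.

Natural logarithms throughout.  Entropies are computed per trial; feature
columns are channel-major with bands ordered delta, theta, alpha, beta
(6 channels × 4 bands = 24 features for the mental-task montage).

## Feature path 2: spectral Granger causality

For the cognitive-task montage the channels are first averaged into five
scalp regions (Fronto-Central, Left Sensorimotor, Central, Right
Sensorimotor, Occipital).  For every ordered region pair a bivariate
VAR(p) is fitted per trial by least squares on demeaned signals, and
Geweke's spectral causality

$$I_{2 \to 1}(f) = -\ln\!\Big(1 - \frac{(\Sigma_{22} -
  \Sigma_{12}^2/\Sigma_{11})\,|H_{12}(f)|^2}{S_{11}(f)}\Big)$$

is averaged over the theta band (4–8 Hz, 0.5 Hz grid) to give one feature
per directed pair (20 features for 5 regions, source-major order).
$S_{11}$ is taken from the model spectral matrix $H \Sigma H^*$.
Residual variances use degrees-of-freedom-corrected divisors so the null
time-domain statistic $F_{2\to1} = \ln(\mathrm{var}(e_1^{R})/
\mathrm{var}(e_1^{U}))$ is approximately unbiased; its population value
for a known VAR(1) is cross-checked in the tests against an independent
Yule–Walker/Levinson–Durbin oracle.  The model order defaults to a fixed
`p = 5` in the feature extractor (the trials are short); a per-pair
minimum-BIC selection over `p = 1..20` is available via `p = NULL`.
Causality is pairwise (bivariate), not conditional on the remaining
regions — conditional causality is out of scope.

## Preprocessing (optional)

An ICA + orthogonalized-EMD stage is provided for the cognitive path:
fixed-point ICA (log-cosh contrast, eigen-whitening, symmetric
decorrelation, seeded and deterministic) and EMD sifting (cubic-spline
envelopes, Cauchy-type stopping `sd < 0.05`, at most 10 sifts per mode and
10 modes) with sequential Gram–Schmidt orthogonalization that preserves
completeness exactly (the residual is recomputed as signal minus modes).
Because no published rule specifies which components feed the connectivity
stage, the default pipeline runs on region-averaged raw signals and the
preprocessing is opt-in: components are retained by a 99% explained-
variance threshold and back-projected when enabled.  Inventing a stricter
selection rule and presenting it as standard would be worse than exposing
the toggle.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable at desk scale with a known
ground truth.

* `gen_mental_eeg()` emulates the mental-task recording geometry
  (6 channels, 250 Hz, 10 s trials): each trial is a sum of band-limited
  Gaussian carriers (4th-order zero-phase Butterworth, ≥ 90% of spectral
  power inside the nominal band) scaled by per-class band powers and
  channel gains plus a broadband noise floor.  It reproduces *band-power
  structure only* — no 1/f background, no transients, no artifacts, no
  inter-channel correlation — so a classifier that separates these classes
  has been shown to read band power, nothing more.
* `gen_coupled_var()` / `gen_two_group_study()` emulate the two-group
  connectivity design (13 patients vs 13 controls, 256 Hz): five region
  signals from a stable VAR(2) whose diagonal terms are damped theta
  oscillators (pole radius 0.95, resonances staggered 5.2–6.8 Hz) and
  whose lag-1 off-diagonal terms carry the directed couplings.  The
  staggered resonances are a conditioning choice: identical high-Q poles
  in every region make the coupled network's stability hypersensitive to
  the coupling weights.  Because the oscillators are high-Q, couplings of
  order 0.01–0.02 already produce theta-band causality of order 0.1–1;
  the patient group halves the designated couplings (F→C, C→F, L→R).
  Subject heterogeneity is a lognormal gain (σ = 0.1) per coupling per
  subject; a subject whose jittered network leaves the stability margin is
  contracted back into it.  Real EEG connectivity is of course not a
  stationary VAR; what the passing tests show is that the estimator chain
  recovers known directed structure, not that it certifies clinical data.
* Every generator is bit-reproducible under a fixed seed, and generated
  VARs are screened for stability (companion spectral radius < 0.98).

## Cross-validation harness

Folds are stratified by class; when subject identifiers are present the
folds are grouped by subject (stratified at the subject level), so no
subject contributes to both a training and a test split of the same fold —
pooling trials of one subject across splits would leak identity
information.  Feature standardization is fitted on the training folds
only.  `k = 5` gives the 80/20 train/test split.  The study sizes used by
the acceptance checks — 80 trials for the two-class band-power study,
26 subjects × 8 trials for the connectivity study, 20 instances for the
solver-oracle comparison — were chosen as the smallest sets at which the
expected effects are comfortably resolved.

## Known limitations

* The literal band map and the nominal Hz edges disagree at
  250 Hz (level-4 nodes are 7.8 Hz wide); both maps are exposed and the
  discrepancy is documented rather than resolved.
* The level-2 node labelled into the beta band spans 62.5–125 Hz at
  250 Hz under the natural-order convention; it is included verbatim in
  the reference map.
* Bivariate (not conditional) causality can report indirect influence as
  direct.
* The sigmoid kernel, non-PSD, is excluded from the default bank.
* `C`, the gap tolerance, the line-search rule and the initialization are
  configurable defaults, not values prescribed by the method.
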