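---
title: "Optimized largest-Lyapunov-exponent features for motor-imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chaolle methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Imagined hand movements desynchronize the sensorimotor alpha/mu rhythm
(ERD), and the complexity of the band-limited EEG changes with them. The
largest Lyapunov exponent (LLE) quantifies that complexity: it is the mean
exponential rate at which two nearby states of the underlying dynamical
system drift apart. A positive exponent indicates chaotic dynamics, a zero
exponent a limit cycle, a negative exponent a stable (contracting) regime.
`chaolle` implements an LLE feature-extraction and classification pipeline
for two-class motor imagery (open hand vs. fist), in which the two
constants every classical LLE recipe hard-codes — the maximum time lag of
the mutual-information (MI) lag search and the maximum embedding dimension
of the false-nearest-neighbor (FNN) search — are treated as free
parameters, tuned per class by population metaheuristics.

## From signal to exponent

Each epoch/channel signal $x_t$ is delay-embedded (Takens) into
$\mathbf{x}_j = [x_j, x_{j+\zeta}, \dots, x_{j+(n-1)\zeta}]$.

**Lag $\zeta$.** MI between $x_t$ and $x_{t+\zeta}$ is estimated on an
equal-width $B \times B$ histogram ($B = 16$ by default) of the
range-normalized series,
$\mathrm{MI}(\zeta) = \sum_{i,s} \Pr_{i,s} \log_2 \frac{\Pr_{i,s}}{\Pr_i \Pr_s}$,
in bits. The selected lag is the first local minimum of the curve over
$\zeta = 1..\zeta_{\max}$, with the global argmin as fallback. Range
normalization makes the curve invariant under affine transforms of the
signal. For a noise-free, exactly periodic tone sampled commensurately the
histogram curve degenerates (the series takes finitely many values) and
the minimum location is a binning artifact; a small amount of measurement
noise restores the canonical quarter-period minimum.

**Dimension $n$.** The Kennel FNN criterion with relative threshold
`rtol = 15`, attractor-size threshold `atol = 2` and a Theiler window equal
to the lag. The selected dimension is the first $n \in [2, n_{\max}]$
whose false-neighbor fraction drops to 1% or below; if none does, the
ceiling $n_{\max}$ itself is used. Dimensions are stepped singly up to 6
and then along a 1.25-geometric ladder, and the number of query points is
capped (the neighbor search always scans all points): both are cost
guards whose only effect is a slightly coarser dimension grid at high
dimension. A series whose fraction stays above 20% for three consecutive
probed dimensions past 6 is declared noise-like and assigned the ceiling
outright.

**Exponent.** Rosenstein-style average log-divergence: every trajectory
point is paired with its nearest neighbor at temporal separation beyond
the Theiler window and with nonzero initial separation; the mean of
$\ln Q_j(i)$ over pairs is tracked for steps $i = 0..i_{\max}$, and the
LLE is the least-squares slope of that curve over the pre-saturation
steps, divided by the sample period $\Delta t$. Two numerical choices
matter:

* *Constant pair set.* The pair population is fixed across the whole
  tracked horizon (pairs that would run off the end of the trajectory are
  excluded from every step, and the horizon is shortened if necessary so
  that at least half the pairs survive). Letting pairs drop out step by
  step changes the composition of the average and biases the slope toward
  zero for nonstationary signals — a decaying oscillation shows a nearly
  flat curve under the varying-pair convention and the correct
  $-\lambda$ slope under the fixed-pair one.
* *Saturation detection.* The fit window ends at the first step where the
  arithmetic mean separation exceeds half the attractor extent (the
  maximum coordinate range). The arithmetic mean saturates earlier than
  the geometric mean, which is the quantity the curve stores; using the
  latter leaves saturated steps inside the fit and underestimates the
  exponent.

The per-signal feature is the composed pipeline
MI lag → FNN dimension → embedding → divergence curve → slope, bounded by
the ceilings $(\zeta_{\max}, n_{\max})$ — deterministic given the signal.

Validation is against independent Jacobian oracles, never against the
estimator itself: the analytic $\ln 2$ exponent of the logistic map at
$r = 4$, the orbit-averaged $\ln|f'|$ for other $r$, Benettin tangent
propagation for the Hénon map and the Lorenz flow, and the closed-form
exponents of linear oscillators.

## Preprocessing

Continuous recordings are segmented into half-open windows
$[\mathrm{cue} - 200\,\mathrm{ms}, \mathrm{cue} + 2500\,\mathrm{ms})$
(0-based sample indices) and each epoch is band-pass filtered at 8–15 Hz
with a 6th-order Butterworth applied forward–backward (zero phase,
effective order 12), in that order. The filter is designed directly in
zero-pole form and realized as second-order sections: the expanded
transfer-function polynomial of this narrow band is numerically unstable
(poles drift outside the unit circle through coefficient rounding). The
squared magnitude response — exactly the forward–backward response — is
applied in the frequency domain on an odd-reflection-padded copy of each
epoch, which matches the behavior of a long-padded time-domain filtfilt
while avoiding its start-up transients. Because the band is narrow the
filter rings for roughly a quarter second; epoch-level filtering therefore
differs from filtering the continuous record by a few percent RMS well
into the epoch, which is why the pipeline filters after segmentation (the
order the method prescribes) and tests only require the two routes to
agree on the trimmed interior.

The analysed channels default to C3 and CP5, the standard left
sensorimotor sites for right-hand imagery.

## The tuners

Three ways to choose the four ceilings
$\theta = (\zeta_{\max}^{open}, n_{\max}^{open}, \zeta_{\max}^{fist}, n_{\max}^{fist})$:

* **traditional** — fixed at $(10, 3, 10, 3)$, the conventional setting.
* **ctw** — Chaotic Tug-of-War. Teams $X_i$ start uniform in the box
  (`X = LB + rand (UB - LB)`). Weights are fitness-affine,
  $W_i = (F_i - F_{worst})/(F_{best} - F_{worst}) + 1 \in [1, 2]$. Each
  ordered pair contributes a displacement
  $\tfrac12 a_{ij} \Delta t^2 + \alpha^k s_{ij} (U_B - L_B)$ with
  $a_{ij} = g_{ij} F_{r,ij} / (W_i \mu)$, $g_{ij} = X_j - X_i$, and
  $F_{r,ij} = \max(W_i\mu, W_j\mu) - W_i\mu$, so only the lighter team of
  a pair moves, toward the heavier. The stochastic factor $s_{ij}$ is
  $\beta(2u - 1)$ with uniform $u$ for plain TW and $2\xi - 1$ with
  $\xi$ a chaotic-map iterate for CTW. Three choices here were genuinely
  open and are worth recording:
  * the stochastic term is centred (two-sided); a strictly positive
    factor is a systematic drift into one corner of the box and cannot
    converge;
  * the "proportional factor" $\alpha$ enters as $\alpha^k$ at iteration
    $k$ (default $\alpha = 0.98$), annealing exploration — with a
    constant-scale term the population can never settle below the noise
    floor;
  * the chaotic map is iterated autonomously by default. The alternative
    mode (`fitnessMix = TRUE`) folds each pair's normalized fitness
    difference into the map state, reading the chaotic searching factor
    literally as a function of $F_i - F_j$; once the population has
    converged those differences collapse and demonstrably destroy the
    map's ergodicity (orders of magnitude worse final error on the
    sphere), so ergodic pure iteration is the default.

  Twelve canonical chaotic maps are built in (Chebyshev, Circle,
  Gauss/mouse, Intermittency, Iterative, Liebovitch, Logistic, Piecewise,
  Sine, Singer, Sinusoidal, Tent), each emitted normalized into (0, 1).
  The tent map uses the 0.7-breakpoint form: the symmetric slope-2 tent is
  degenerate in binary floating point (every dyadic orbit reaches 0).
  Orbits that collapse onto a fixed point or short cycle raise an error
  suggesting a different seed state.
* **wd** — Intelligent Water Drop over a layered graph (one layer per
  ceiling, nodes = candidate integers). Drops pick one node per layer
  with probability inversely monotone in soil, gain velocity on low-soil
  edges, erode the soil they traverse, and the best path found so far is
  eroded globally each iteration. Two stabilizers proved necessary:
  purely subtractive soil updates (the textbook multiplicative form lets
  quality-blind visit-popularity dominate the quality signal), and a
  relocation step that drops a newly found best path's nodes below the
  current layer minima (otherwise a long-eroded incumbent keeps
  attracting the drops no matter what was just discovered). An
  $\varepsilon$-uniform exploration draw per layer (default 0.15) keeps
  the search alive after lock-in.

All methods minimize, stop at a hard evaluation budget (10,000 by
default, counted per cost-function call with no exemptions), round
integer coordinates at evaluation time only, and are reproducible from a
seed.

**The cost function.** The method's own papers do not state one. The
package uses either 1 minus a stratified k-fold SVM accuracy or, as a
cheap surrogate, the negative Fisher ratio of the features, evaluated on
a small stratified subsample of the optimizer-visible partition. One
design point is deliberate: the per-class ceilings are applied to *every*
epoch as two parallel feature maps (2 channels × 2 parameter sets = 4
features), never keyed by the epoch's own label. Keying extraction on the
true label would let any asymmetric $\theta$ fabricate class separation
at test time; with label-free maps the label enters only the fitness
score. A tuned $\theta$ is accepted only if it beats the traditional
setting on the optimizer's own objective.

## The classifier

A soft-margin C-SVM with the generalized RBF kernel
$K(x, z) = \exp(-\lVert x - z\rVert^{\tau} / (2\sigma^{\tau}))$, with
width $\sigma$ (median-heuristic default), shape $\tau \in (0, 2]$
($\tau = 2$ is the standard Gaussian; $\tau$ above 2 is rejected because
the kernel family stops being positive definite, and the Gram matrix is
eigenvalue-checked at training as a second line of defense), and a center
translation applied to the features before kernel evaluation. The dual is
solved by `kernlab::ksvm` on the precomputed Gram matrix; at $\tau = 2$
the decision values coincide with kernlab's own Gaussian kernel to
numerical precision, which the tests use as an independent reference.

Features are screened by a two-sided paired t test between the classes
(pairs matched by within-class rank — the pooled synthetic epochs carry no
subject structure); features with $p < 0.05$ advance, and if none does the
best-p feature is retained with a warning. The canonical split is a
stratified random 70/25/5 (train/test/validation) with largest-remainder
rounding against global targets, so 100 rows split exactly 70/25/5; the 5%
validation part is never used for any selection.

**Accuracy reporting and leakage.** Each pipeline run first makes one
stratified 70/30 split into an optimizer-visible partition and a holdout.
The tuner only ever evaluates cost on (a subsample of) the former. The
reported accuracy is the mean over `nRepeats` repeats, each retraining on
a fresh stratified 80% of the visible partition and scoring the entire
holdout; averaging over training subsets integrates out training noise,
which matters for the no-effect (null) behavior of the report.

## The synthetic generators

Canonical systems (logistic, Hénon, Lorenz with fixed-step RK4 at
$dt = 0.01$, pure sine, damped oscillator) provide orbits with
independently known exponents. The two-class epoch generator emulates:

* an alpha carrier at a random frequency in 8–13 Hz with random phase;
* ERD: the fist class's amplitude drops by `erdDepth` (default 0.5) after
  the virtual cue, with a 100 ms linear ramp;
* a chaoticity difference: a logistic-map series with class-dependent
  growth rate (defaults $r = 3.9$ open vs $3.6$ fist), iterated at the
  sampling rate, band-limited to the alpha band, normalized to unit
  variance and mixed at weight `chaoticMix` (default 0.6). Band-limiting
  is essential twice over: a raw map series is broadband and the 8–15 Hz
  pipeline filter would remove nearly all of it, and a filtered chaotic
  observable needs a higher embedding dimension than the bare map — which
  is precisely what makes the dimension ceiling a live parameter for the
  tuners to find. Under these conditions the traditional $(10, 3)$
  ceilings underembed the planted dynamics and barely discriminate, while
  larger ceilings separate the classes clearly; passing tests show the
  pipeline finds structure *when embedding ceilings are what hides it*,
  not that real EEG behaves this way;
* pink (1/f-amplitude) noise at `noiseSigma` (default 0.5), generated by
  spectral shaping of white noise.

Per-channel streams are seeded independently from (seed, channel name),
so a channel's content does not depend on which other channels were
requested. The generator does not model volume conduction, artifacts
(EOG/EMG), nonstationary background spectra, or inter-subject
variability; results on it bound what the code can do, not what EEG data
will yield. The sampling rate default (512 Hz) is a conventional headset
rate; the tests and the acceptance script run the pipeline at 128 Hz
(2.7 s epochs of 346 samples), a standard BCI rate that keeps the
simulations compact.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 5000-point orbits for the
map exponents; 10–20 optimizer seeds at the full 10,000-evaluation budget
for the sphere and planted-recovery checks; and pipeline comparisons on
200 epochs/class at 128 Hz with a 500-evaluation tuner budget, the Fisher
surrogate on 8 epochs/class, and 8 accuracy repeats. Null-safety runs use
the same sizes with the class difference switched off.

## Known limitations

* The divergence-curve estimator needs hundreds of points per epoch;
  below ~1 s of data at 128 Hz the neighbor statistics get thin.
* The FNN dimension ladder is coarse above dimension 6 (by design, for
  cost); exact minimal dimensions above 6 are not resolved.
* Filtered, noisy signals often never reach the 1% FNN threshold, in
  which case the ceiling itself is selected — the feature then measures
  divergence in a partially unfolded space. This is intended (it is what
  makes the ceilings informative) but means the reported exponents are
  pipeline quantities, not physical invariants of the underlying system.
* The paired t-test screen assumes matched pairs; with pooled epochs the
  within-class-rank pairing is a convention, not a subject pairing.
* Accuracy comparisons between tuners share a single holdout per run;
  they are comparable within a run, not unbiased absolute estimates.
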