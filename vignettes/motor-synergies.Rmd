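---
title: "Modular analysis of locomotor EMG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular analysis of locomotor EMG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergait)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter and why they
default to what they do, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The modular-control model

The working hypothesis of muscle-synergy analysis is that the central
nervous system does not command every muscle independently; it combines a
small number of time-invariant muscle groupings (**motor modules**, the
columns of $W$) with shared time-varying activation coefficients (**motor
primitives**, the rows of $H$). For a nonnegative EMG-envelope matrix $V$
(12 muscles $\times$ 200 points per gait cycle $\times$ cycles), the model
is the low-rank factorization

$$V \approx V_R = W H, \qquad W \in \mathbb{R}^{m \times r}_{\ge 0},\;
H \in \mathbb{R}^{r \times n}_{\ge 0}.$$

Nonnegativity is not a numerical convenience: envelopes are rectified
signals and muscle contributions are additive drives, so parts-based
nonnegative factors are the physiologically interpretable decomposition.

### Fitting

`nmf_factorize()` uses the classical multiplicative updates for the
Gaussian (Frobenius) objective, updating $H$ with the current $W$ and then
$W$ with the freshly updated $H$. Multiplicative updates preserve
nonnegativity at every iteration by construction. Both denominators carry
an additive guard $\varepsilon = 10^{-12}$ because upstream processing may
legitimately produce all-zero rows (a degenerate channel is zeroed, not
dropped, to keep $m = 12$); for non-degenerate inputs the results are
insensitive to $\varepsilon$ (checked to $10^{-6}$ in the tests).

Convergence is monitored on the reconstruction
$R^2 = 1 - \|V - WH\|_F^2 \,/\, \|V - \bar V\|_F^2$, where $\bar V$ is the
grand mean over all entries: the iteration stops when the *relative*
change of $R^2$ across the last 20 iterations drops below $10^{-4}$
(0.01%), with a cap of 1000 iterations. Two readings were possible here
and both are defensible: "0.01%" as relative or as absolute change. We
chose relative; at the $R^2 \approx 0.9$ typical of these fits the two
differ by a factor of ~1.1 and change stopping iterations only marginally.
Similarly, $R^2$ could pool variance over all entries or average
per-muscle coefficients; we pool, treating $V$ and $V_R$ as single data
sets, which keeps the quantity monotone in the Frobenius objective the
updates minimize.

The factorization engine is compiled (RcppArmadillo) because a full rank
sweep runs 90 factorizations of a $12 \times 6000$ matrix per trial;
initial matrices are drawn in R under `set.seed()`, uniformly in (0, 1),
so determinism follows R's RNG contract and a fixed seed reproduces a
decomposition bit for bit.

### Rank selection

The number of synergies is not known in advance. `extract_synergies()`
fits ranks 1–9 (9 being the rounded 75% of 12 muscles — extracting as many
synergies as muscles would defeat dimensionality reduction), each as the
best of 10 random restarts, and passes the $R^2$-versus-rank curve to
`select_rank()`: fit a simple linear regression, and while the residual
mean squared error is at least $10^{-4}$ and more than two points remain,
drop the lowest-rank point and refit. The chosen rank is the first point
of the surviving (most linear) segment — the elbow past which adding
synergies buys only noise-level improvement. The procedure is exactly
reproducible by hand, and the tests pin it to hand-executed oracles.

## Higuchi fractal dimension

The local complexity of a primitive $H(1), \dots, H(n)$ is estimated from
how its measured "length" scales with the sampling lag $k$. For offsets
$t_0 = 1 \dots k$ the decimated curve length is

$$L_{t_0}(k) = \frac{1}{k} \left[ \sum_{i=1}^{\lfloor (n-t_0)/k \rfloor}
\left| H(t_0 + ik) - H(t_0 + (i-1)k) \right| \right]
\frac{n-1}{\lfloor (n-t_0)/k \rfloor \, k},$$

and $L(k)$ is the mean over offsets. If $L(k) \propto k^{-\mathrm{HFD}}$,
the OLS slope of $\log L(k)$ on $\log(1/k)$ estimates the fractal
dimension: exactly 1 for a straight line (the closed form gives
$L(k) = (n-1)/k$), approaching 2 for white noise. The estimate is exactly
amplitude-invariant because the series is min-subtracted and
max-normalized first — and would be invariant regardless, since amplitude
scaling shifts only the intercept of the log–log line.

Two deliberate choices:

- **Lag range $k = 1 \dots k_{\max}$, default $k_{\max} = 10$.** A
  stricter reading of the interval constraint ("$2 < k < k_{\max}$")
  would discard the smallest lags, contradicting both canonical usage of
  the estimator and the choice of $k_{\max} = 10$ as the linear region of
  the log–log plot for 6000-point primitives. We default to the canonical
  full range and expose `k_min` for users who want the alternative.
- **Whole-primitive HFD.** The dimension is computed on the full
  concatenated primitive (6000 points for 30 cycles), one value per
  primitive, then averaged into one value per trial. Combined synergies
  are *included* here (they are excluded only from FWHM), because
  complexity is well-defined regardless of functional identity.

Validation uses three independent anchors: the linear-ramp closed form
(machine precision), seeded white noise (mean over 100 seeds in
[1.90, 2.05]), and fractional Brownian motion synthesized by Davies–Harte
circulant embedding, whose theoretical dimension $2 - H$ is recovered
within 0.15 for Hurst exponents 0.2, 0.5 and 0.8.

## Full width at half maximum

`fwhm_cycle()` subtracts each cycle's minimum and counts the points at or
above half the cycle maximum. The counting convention was open: "points
exceeding" read literally is a strict inequality, but then a cycle whose
peak is a single sample at exactly twice the second level can lose its
peak from the count. We default to `>=` (the peak always counts) and
expose `"gt"`; on smooth primitives the two differ by at most ~2 points.
Constant cycles have no half maximum: they yield `NA` and are excluded
from the per-primitive mean rather than poisoning it; a primitive with
*no* defined cycle is an error. FWHM is reported only for fundamental
synergies — combined primitives blend two activation peaks and their
width has no single-burst interpretation.

## Functional classification

Primitives from all trials of a condition are reduced to mean 200-point
cycles (min-subtracted, max-normalized) and pooled. We cluster mean
cycles rather than full 6000-point traces: principal shapes are
cycle-level concepts, and the reduction averages out cycle-to-cycle
jitter that would otherwise smear the basis curves. The pool is
transposed (time points $\times$ primitives) and run through the same NMF
extraction machinery with candidate ranks up to the maximum observed
factorization rank plus one; the basis curves are the **principal
shapes**, rescaled to maximum 1 with the compensating factor absorbed
into the weights (the NMF scale indeterminacy makes this a pure
convention).

Classification is two-step. A primitive's candidate shape is the one
carrying its largest weight, admitted only if that weight reaches the
grand mean of the whole weight matrix ("average of all weights" read
literally; a per-shape mean is a plausible alternative and the admission
rule is deliberately isolated in the code). Admitted primitives must then
achieve an $R^2$ against their candidate shape of at least 25% of the
average $R^2$ of the *other* admitted primitives against their own shapes
— four times that average when it is negative. The reference average
excludes the primitive under test and is evaluated once, not iterated to
a fixed point: a fixed-point variant could oscillate and the single pass
is the simplest consistent reading. Everything else is **combined**.

Shapes are named from their 0-based peak phase on the 200-point cycle
(stance is points 0–99, and a boundary peak at point 100 resolves to the
stance side): greedy nearest-prototype matching against peak phases 25,
75, 125, 175 (weight acceptance, propulsion, early swing, late swing),
closest pair first. The prototype fallback also covers conditions where
fewer than four shapes emerge — real cohorts do show missing fundamental
synergies at some speeds — and identical peak indices are disambiguated
by center of mass.

## The synthetic generator

`synth_spec()`/`synthesize_normalized_emg()`/`synthesize_raw_trial()`
invert the analysis model to produce ground-truthed data:

- **Primitives**: one Gaussian bump per synergy per cycle, centered at
  phases 25/75/125/175 with seeded cycle-to-cycle jitter (sd 2 points),
  width $\sigma = 18$ points by default ($\mathrm{FWHM} =
  2\sqrt{2\ln 2}\,\sigma \approx 42$ normalized points, mid-range for
  locomotor primitives). Bumps are wrapped circularly as a sum of
  periodic Gaussian images — late-swing activity genuinely continues
  through the touchdown — which keeps the curve smooth at the cycle
  boundary; a minimal-distance wrap would plant a derivative kink at the
  antipode that contaminates complexity estimates of very wide bumps.
  `width_scale` multiplies all widths and serves as a speed surrogate.
- **Modules**: `"G1-like"` and `"G2-like"` presets encode the
  distance-runner and sprinter muscle groupings (e.g. plantarflexors
  dominant in propulsion for G1, gastrocnemius medialis shifted toward
  weight acceptance and hamstrings shared with propulsion for G2, reduced
  tibialis anterior in late swing for G2), or any explicit nonnegative
  matrix, column-normalized to maximum 1.
- **Noise**: additive Gaussian noise (sd 0.02 by default) on the envelope
  matrix for stage-level tests; the raw-signal path instead multiplies
  the envelope onto band-limited (10–500 Hz) carrier noise, emulating the
  interference-pattern EMG a 2 kHz acquisition chain with a hardware
  band-pass would record, plus a square-wave vertical force (800 N during
  stance, stance fraction 0.6 of a 1 s cycle) aligned with the emitted
  gait events.
- **Planted combined synergies**: with probability `blend_fraction` one
  primitive is replaced by the renormalized sum of its own and another
  synergy's bump, and labelled combined in the ground truth.

What the generator does **not** emulate: motor-unit physiology (action
potentials, volume conduction), amplitude asymmetries between stance and
swing of real primitives (walking primitives are skewed, running ones
symmetric), electrode artifacts, crosstalk, and non-stationarity across a
trial. Passing recovery tests on this generator therefore demonstrates
that the pipeline is correct *for data obeying its own model* — rank
recovery, module fidelity, width/complexity mechanics — not that real
EMG satisfies the model.

## Numerical choices and degenerate inputs

- Zero-phase filtering is forward–backward (`signal::filtfilt`), so the
  effective magnitude response is the squared order-4 Butterworth; tiny
  negative low-pass ringing is clipped to zero before factorization.
- Linear interpolation for the 200-point time normalization: the
  least-assumption, shape-preserving choice; stance always occupies the
  first 100 points of a cycle regardless of the true stance fraction.
- Constant channels normalize to all-zero and are flagged, not dropped.
- Cadence counts two steps per gait cycle (single-limb cycle timing).
- Gait-event defaults (30 N threshold, 50 ms minimum contact) follow
  common force-plate practice; the detector is a deliberate simple
  stand-in for dedicated event-detection algorithms.
- Amplitude normalization precedes time normalization, following the
  stated processing order of the chain.
- Restart seeds in a rank sweep are `base_seed + (rank-1)*n_restarts +
  restart`, so every factorization is independently and reproducibly
  seeded.

## Problem sizes in the tests

Unit tests exercise the contracts on small instances (3–10 cycles,
600–2000 points) where oracles are exact; the calibration and recovery
suite runs at the study scale the metrics are specified for — 6000-point
series for the fractal-dimension landmarks, ten 30-cycle, 12-muscle
trials at noise sd 0.02 for the rank-recovery and module-fidelity check,
and 30-cycle noiseless sweeps over `width_scale` 0.5–2 for the
width–complexity mechanism. These sizes were chosen as the smallest at
which each property is stated, keeping the full suite runnable in a few
minutes on a laptop.

## Known limitations

- The force-threshold event detector is not a validated gait-event
  algorithm; with real force plates, prefer dedicated methods and feed
  the resulting cycle times in via `read_cycle_times()`.
- The classifier clusters each condition's pool independently; shapes are
  not transferred across conditions, and cross-condition label identity
  relies on the prototype phases.
- HFD values depend on `kmax` and on series length; comparisons are only
  meaningful at fixed settings (the defaults fix both).
- The RData adapter is read-only and expects the deposited
  list-of-trials layout; the package's native interchange formats are
  delimited text plus JSON sidecars.
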