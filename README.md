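# synergait

Muscle synergy extraction and motor primitive analysis for locomotor EMG.

`synergait` is an R package for researchers in motor control and
biomechanics who record multi-muscle surface EMG during treadmill walking
and running and want a complete, reproducible modular-control analysis:
from raw signals to muscle synergies, and from synergies to the
complexity, duration and functional identity of their temporal activation
patterns. It also ships a ground-truthed synthetic generator of modular
gait EMG, so every stage of the pipeline can be validated without any
recordings.

## The analysis in brief

**Preprocessing.** The 12 ipsilateral lower-limb muscles (MA, FL, RF, VM,
VL, ST, BF, TA, PL, GM, GL, SO) are high-pass filtered at 50 Hz,
full-wave rectified and low-pass filtered at 20 Hz (4th-order zero-phase
Butterworth) to obtain linear envelopes; each channel is min-subtracted
and normalized to its trial maximum; each gait cycle is time-normalized
to 200 points (100 stance + 100 swing) and 30 cycles are concatenated
into the nonnegative matrix *V* (m = 12 muscles × n = 6000 points).

**Synergy extraction.** *V* is factorized as *V* ≈ *V*<sub>R</sub> = *WH*
by non-negative matrix factorization with multiplicative updates

- *H* ← *H* ∘ (*Wᵀ V*) / (*Wᵀ W H*)
- *W* ← *W* ∘ (*V Hᵀ*) / (*W H Hᵀ*)

where *W* (m × r) holds the **motor modules** (time-invariant muscle
weights) and *H* (r × n) the **motor primitives** (time-dependent
activation coefficients). Convergence is declared when the reconstruction
R² changes by less than 0.01% over 20 iterations. Each candidate rank
r = 1…9 is fitted from 10 random restarts, keeping the best R²; the rank
is then selected by iteratively fitting a line to the R²-versus-rank
curve and dropping its first point until the residual mean squared error
falls below 10⁻⁴ (or two points remain) — the chosen rank is the first
point of the most linear part of the curve.

**Primitive metrics.** The local complexity of each motor primitive is
its Higuchi fractal dimension: curve lengths
*L*(*k*) for lag *k* = 1…10 are computed from decimated subseries and the
HFD is the OLS slope of log *L*(*k*) versus log(1/*k*) — exactly 1 for a
smooth linear series, near 2 for white noise, and independent of signal
amplitude. Primitive duration is the full width at half maximum (FWHM):
per cycle, the number of points at or above half the min-subtracted
cycle maximum, averaged over cycles (fundamental synergies only).

**Functional classification.** Mean-cycle primitives from all trials of a
condition are pooled and clustered with the same NMF machinery (maximum
rank = maximum observed factorization rank + 1) into "principal shapes".
A primitive is fundamental if its largest weight reaches the average of
all weights and its R² against the candidate shape reaches 25% of the
average R² of the other clustered primitives (4× when that average is
negative); otherwise it is a **combined** synergy. Fundamental shapes are
named weight acceptance, propulsion, early swing or late swing from their
peak phase in the gait cycle.

**Gait parameters.** Touchdown/lift-off detection from a vertical force
threshold, cadence (two steps per cycle), stance/swing times, and the
strike index (heel-to-center-of-pressure distance over foot length;
≤ 0.33 rearfoot, 0.34–1.00 mid/forefoot).

## Worked example

Simulate one 30-cycle running trial with four planted synergies and run
the whole chain (filtering → normalization → NMF rank sweep → HFD →
classification → FWHM):

```r
library(synergait)

spec  <- synth_spec(n_cycles = 30, noise_sd = 0.02, seed = 7)
trial <- synthesize_raw_trial(spec)

report <- run_trial(list(raw = trial$raw, events = trial$events,
                         id = "demo"), synergy_config(seed = 1))
report
#> <trial_report> demo: rank 4 (R2 0.966), HFD 1.117, labels: early_swing, propulsion, weight_acceptance, late_swing
report$fwhm
#>       early_swing        propulsion weight_acceptance        late_swing
#>          41.13333          40.76667          40.86667          41.76667
report$gait
#> <gait_parameters> cadence 120.0 steps/min, stance 0.600 s, swing 0.400 s (30 cycles)
```

The report says: the rank-selection heuristic recovered the four planted
synergies (reconstruction R² = 0.966 at rank 4); all four primitives were
classified as fundamental, one per locomotor function; their mean trial
HFD of 1.12 marks smooth, low-complexity activation curves; and each
primitive is active for about 41 of the 200 normalized time points per
cycle — matching the generator's planted bump width (σ = 18 points,
FWHM = 2√(2 ln 2)·σ ≈ 42).

Cohort-level runs (`run_cohort()`) pool the primitives per condition,
classify them together, and emit tidy tables (rank, HFD, FWHM,
occurrence counts, combined fractions) ready for any statistics tool.
A command-line wrapper lives in `inst/scripts/synergait-pipeline.R`.

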