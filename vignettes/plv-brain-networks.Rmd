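---
title: "Phase-locking-value brain networks: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking-value brain networks: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

This vignette is the package's own account of its science: what is being
modelled, which knobs matter, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The measurement model

The pipeline targets resting-state EEG functional connectivity in a
within-subject crossover: two conditions (exercise with vs. without music)
by two times (pre vs. post exhaustion), with source-level signals averaged
into regions belonging to five resting-state networks (sensorimotor SMN,
dorsal attention DAN, salience SN, central executive CEN, default mode
DMN).

Connectivity is the phase locking value. For two band-limited signals with
instantaneous phases $\varphi_X(t), \varphi_Y(t)$,

$$\mathrm{PLV} = \left| \frac{1}{T}\sum_{t=1}^{T}
  e^{i(\varphi_X(t) - \varphi_Y(t))} \right| \in [0, 1],$$

estimated per 6-s segment and averaged across segments. The measurement
chain is: zero-phase Butterworth band-pass (theta 4–8 Hz, alpha 8–14 Hz,
beta 14–30 Hz; order 4 per pass, applied forward–backward so the effective
attenuation one band away exceeds 20 dB), segmentation into non-overlapping
6-s windows (trailing remainder discarded), analytic-signal phase
extraction per segment, and PLV per region pair. The first and last 5% of
each segment's samples are excluded from the phase average to suppress
filter and Hilbert edge transients. Sampling-rate default is 256 Hz.

Two details are deliberate conventions rather than consequences of the
estimator:

* **Per-segment averaging.** PLV is computed per segment and the moduli are
  averaged, matching the segmented acquisition and making the estimate
  robust to slow nonstationarity. The alternative (one PLV over the pooled
  samples) weights long-range phase drift differently and was rejected.
* **Diagonal convention.** PLV matrices store 1 on the diagonal but every
  downstream statistic (total average, strengths, thresholding) excludes
  self-connections.

Because moduli of segment phasors are averaged, two independent regions do
not measure 0: each 6-s segment contributes a positive Rayleigh-type bias,
so the zero-coupling expectation (the *floor*, `plv_floor()`) is roughly
flat in the number of segments (about 0.13–0.15 for the default bands) and
only the *spread* shrinks as $1/\sqrt{n_\text{segments}}$. All calibration
logic is built around this floor rather than around zero.

## The synthetic generator

No public recordings exist for this design, so the generator is a
first-class module, not a test fixture. It emulates:

* the 2×2 crossover with a configurable number of subjects (default 34)
  and regions (default 78);
* band-specific baseline coupling with plantable condition×time effects on
  arbitrary edge sets (additive PLV deltas, clipped to $[0,1]$ with a
  message when clipping occurs);
* between-subject heterogeneity as a truncated-normal coupling shift
  (default sd 0.03, truncated at two sds) shared across a subject's four
  cells — a subject random effect that paired contrasts cancel.

**Signal model.** Region signals are white-noise sources mixed through the
square root of a latent correlation matrix and then band-passed by the
measurement chain itself. The latent correlation $r$ of a pair maps
monotonically to its measured PLV; `calibrate_coupling()` inverts this map
by bisection against a simulation oracle (`plv_response()`, memoised per
band/rate/segmentation configuration) to a tolerance of 0.01 PLV, and
`calibration_curve()` provides the same map as one invertible interpolant
so a whole heterogeneous target matrix needs a single grid of oracle
evaluations rather than one bisection per entry. A target of exactly 1 maps
to $r = 1$ (duplicated signals), targets at or below the floor map to
$r = 0$, and targets below the floor raise an error reporting the floor.

A single shared-phase oscillator cannot jointly realize the planted
configurations this package needs (for example a strongly coupled clique on
top of a uniform background): one common phase forces an essentially
rank-one coupling structure. The latent-correlation model realizes every
target matrix whose calibrated latent matrix is positive semidefinite;
infeasible targets fail loudly, naming a region triple whose 3×3 principal
minor is negative.

**Two generation modes.** `simulate_group(mode = "signal")` runs every
matrix through the full signal pipeline and is the fidelity reference;
`mode = "matrix"` samples on the PLV scale directly (target + subject shift
+ edgewise Gaussian measurement noise, default sd 0.02, the empirical scale
of segment-averaged PLV error at 50 segments). Matrix mode exists because
the calibration studies — hundreds of repetitions at 34 subjects × 78
regions — are orders of magnitude beyond what signal synthesis allows at
test time; it is statistically matched (uniform null p-values, calibrated
paired t-tests) but does not inherit signal-level artefacts such as the
floor's dependence on band or any phase-model misfit. Conclusions that
depend on those features are always checked in signal mode at reduced size.

**What the generator does not emulate:** volume conduction or source
leakage (PLV's known vulnerability), 1/f background spectra, amplitude
dynamics, artifacts, or any spatial embedding of the regions. Passing tests
therefore validate the *analysis chain*, not robustness of PLV to leakage
on real EEG.

## Graph metrics

Weighted matrices are binarized at each sparsity level $s$ of the grid
0.06–0.50 (step 0.02, 23 levels) by retaining the
$\mathrm{round}(s \cdot N(N-1)/2)$ strongest edges — round half away from
zero; ties at the cut are broken by (weight descending, row, column), so
thresholding is deterministic. Metrics per binary graph:

* $C_p = \frac{1}{N}\sum_i E_i / \binom{D_i}{2}$ (triangle density around
  each node); nodes with degree < 2 contribute 0 rather than 0/0.
* $L_p$: mean shortest-path length over *connected* ordered pairs.
  Disconnected pairs are excluded — global efficiency, which handles
  disconnection natively, is the complementary integration measure.
* $E_{glob} = \frac{1}{N(N-1)}\sum_{i \ne j} 1/L_{ij}$ with
  $1/L_{ij} = 0$ for disconnected pairs.
* $E_{loc}$: mean over nodes of the global efficiency of each node's
  neighbourhood subgraph; degree < 2 contributes 0.
* $\gamma = C_p/C_{random}$, $\lambda = L_p/L_{random}$,
  $\sigma = \gamma/\lambda$ (an exact identity in the code), with null
  means over degree-preserving rewired surrogates (double-edge swaps,
  $10\,|E|$ attempted swaps each; degree sequences asserted per
  surrogate). At very sparse levels a surrogate set can be triangle-free
  ($C_{random} = 0$); $\gamma$ and $\sigma$ are then undefined at that
  level and recorded as `NA` rather than infinite.

Across the grid each metric is aggregated as trapezoidal area under the
metric-vs-sparsity curve divided by the grid width, which keeps the
aggregate on the metric's own scale (a constant profile aggregates to that
constant) and drops undefined levels. How the original study collapsed its
23 levels into per-condition scalars is not stated; normalized AUC is this
package's choice, and aggregate values of dense synthetic PLV graphs (e.g.
$E_{glob}$ near 0.5–0.6) are accordingly not comparable to any particular
published scalar.

## NBS and the statistics layer

The Network-Based Statistic implementation tests paired connectome
contrasts: per-edge paired t over subject differences, thresholding at
edge $p < 0.001$ (two-sided by default, components formed separately per
t sign), connected components among suprathreshold edges, and a null
distribution of the maximal component edge count obtained by within-subject
sign flips of the difference matrices — the standard exchangeability scheme
for a paired design. Component size is edge count (not intensity).
Corrected p-values use $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$,
never exactly zero; when $2^n \le n_{perm}$ the full sign-flip set is
enumerated and the test is exact. Edges whose differences are constant and
non-zero have no defined t and are flagged and excluded; identical inputs
(all differences zero) give $t = 0$ — no evidence — rather than an error.

The inference layer mirrors the study's tests:

* **2×2 repeated-measures ANOVA** with subject-by-effect error strata:
  each within-subject effect is tested against its own subject interaction,
  df $(1, n-1)$, with partial $\eta^2 = SS_e/(SS_e + SS_{err})$. With
  1-df effects sphericity is moot, so no correction is applied. Normality
  screening is out of scope and a user responsibility.
* **Friedman** with midranks and tie-corrected denominator
  $(k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$; an exact within-row
  permutation p is available while $(k!)^n \le 250{,}000$ (the full
  enumeration for, say, 4 conditions at study size would exceed $10^{11}$
  combinations and is not offered).
* **Dunn post hoc** from mean-rank differences with
  $SE = \sqrt{k(k+1)/(6n)}$, two-sided normal p, Bonferroni multiplier
  equal to the number of pairs (6 for four conditions).
* **Min-max normalization** of each strength measure is pooled per band
  across all subject × condition × time values, so the four compared cells
  share a scale; the pooling scope is a package choice. Hemisphere is not a
  partition dimension.

## Problem sizes and numerical choices

The default parameters are the study's: 34 subjects, 78 regions, 6-s
segments at 256 Hz, 23 sparsity levels, 1000 surrogates per level, NBS at
0.001/0.05 with 2000 permutations. The shipped test-and-driver runs scale
down where the full sizes would add nothing but wall-clock time, as the
package's own choice of desk-scale defaults: calibration studies use
matrix-mode generation (200 null datasets at 34 × 78 with 500
permutations), the end-to-end signal-mode recovery runs use 8–10 subjects,
24–30 regions and 120-s recordings (20 segments), and drivers use 25
surrogates per sparsity level. Every stochastic stage draws its seeds from
one root via `derive_seeds()`, and pipeline manifests record MD5 content
hashes — identical configs reproduce identical hashes.

Numerical details worth knowing: the analytic signal is computed by the
frequency-domain Hilbert method; the latent-matrix square root uses an
eigendecomposition with negative eigenvalues clipped at zero (so an exactly
singular target, e.g. a duplicated region, still simulates); calibration
curves are made monotone by an isotonic pass before inversion; and
edge-count rounding uses round-half-away-from-zero so that, e.g., sparsity
0.06 on 78 nodes keeps exactly 180 edges.

## Known limitations

* PLV is sensitive to residual zero-lag leakage; leakage-robust metrics
  (wPLI, imaginary coherence) are intentionally out of scope.
* The generator's noise model is Gaussian and stationary; real EEG is
  neither. Calibration results transfer to real data only to the extent
  that segment-averaged PLV noise is approximately Gaussian at 50 segments.
* The shipped 78-region partition is synthetic (the five-network membership
  of a real parcellation must be supplied by the user), and planted effect
  magnitudes are user-set — the study reports no effect sizes on the PLV
  scale to emulate.
* Weighted-graph metrics, nodal/hub statistics, F-based NBS for more than
  two groups, and figure rendering are non-goals.
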