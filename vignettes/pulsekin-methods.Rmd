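---
title: "Quantifying pulsed swimming in medusae: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsed swimming in medusae: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsekin)
```

## The measurement model

Scyphozoan medusae swim by rhythmic bell pulsation. From a digitized
recording — apex coordinates $(x_i, y_i)$ at times $t_i$, optionally with
bell height $h_i$ and diameter $D_i$ — four instantaneous quantities
describe the mechanics:

* **fineness** $f_i = h_i / D_i$, the bell shape index ($f < 1$ oblate,
  $f > 1$ prolate);
* **displacement** $m_i = \sqrt{(X_f - X_i)^2 + (Y_f - Y_i)^2}$ between
  successive frames;
* **velocity** $u_i = m_i / \Delta t_i$;
* **Reynolds number** $Re_i = D_i u_i / \nu$, computed in SI units, with
  the kinematic viscosity of seawater defaulting to a temperature table
  (1.17, 1.05, 0.95 $\times 10^{-6}\,$m$^2\,$s$^{-1}$ at 15, 20, 25 °C,
  linearly interpolated and clamped) overridable by an explicit value.

All internal units are centimetres and seconds, the natural scale of
these animals; the cm→m conversion happens only inside
`reynolds_series()`. Displacement, velocity and Reynolds number are
*interval* quantities; where an interval needs a diameter, the two
endpoint frames are averaged (symmetric, unbiased for a smooth $D(t)$).
Records without bell measurements — common for literature-extracted
data — get `NA` fineness and Reynolds series but full velocity metrics.

## Pulse cycles and phases

Each pulsation cycle is split into three phases: **contraction** (onset
of pulsation to the velocity peak, which coincides with the minimum bell
diameter), **relaxation** (velocity peak to full bell re-expansion,
i.e. the first maximum-diameter point after the peak), and the
**interpulse** coast, during which the stopping vortex produces a
secondary velocity gain while the bell stays expanded. Passive energy
recapture (PER) is the mean interpulse distance divided by the mean
cycle displacement; sequence-level pulsation frequency is pulses per
elapsed time and requires at least two pulses (the reciprocal mean
period is also reported, as `P_freq_alt`).

Published velocity profiles give no operational detection rule, so the
rules here are explicit and exposed as parameters:

* a velocity maximum is a pulse peak if its topographic prominence is at
  least `prominence` (default 0.25) times the 5th–95th percentile span
  of the velocity series;
* peaks shorter than `height_frac` (default 0.6) of that span above the
  valley floor are discarded when at least two tall peaks exist — this
  removes the secondary recapture bump, a genuine local maximum that is
  not a new pulse (the rule assumes the bump stays below roughly half
  the peak-to-trough range, as in published profiles);
* remaining peaks closer than `sep_frac` (default 0.6) of the dominant
  period to a taller peak are dropped;
* the cycle onset is the last near-floor local velocity minimum before
  the peak. Ties on an exactly flat coast resolve to the *last* flat
  sample, where the rise begins; other extremum ties resolve earliest.
* when the velocity peak and the diameter minimum disagree (they
  "usually" coincide), the velocity peak defines the contraction end and
  the offset is reported as the per-cycle diagnostic `peak_offset_s`.

Edge-truncated cycles are discarded: $k$ accepted peaks yield $k-1$
complete cycles. A constant-velocity glide returns an empty cycle list —
a signal, not an error.

## Ensemble (phase-folded) refinement

Digitization jitter sets the accuracy limit for phase boundaries: a
velocity trough on a flat coast is localized by a single noisy sample.
`analyze_sequence()` therefore refines the per-sequence summary from the
**ensemble-averaged cycle**: all cycles are folded peak-aligned onto a
fine lag grid (cycles sample the cycle phase at offsets incommensurate
with the period, so the average resolves structure below one sampling
interval), each cycle is re-registered against the folded profile by
least squares (sample-argmax alignment jitters asymmetrically when the
rise is steeper than the fall), velocity *components* are folded and the
norm taken afterwards (removing the upward bias of averaging
$|v + \varepsilon|$), and the folded profile is summarized by a
least-squares fit of the same piecewise raised-cosine pulse template the
synthetic generator uses, with the known smoothing/differencing kernels
applied to the template basis. Phase distances are integrals of the
folded velocity between the fitted boundaries.

On clean data the ensemble estimates agree with the plain across-cycle
means to within a sample; under jitter they are far more robust. The
template is the package's own pulse-shape family; for profiles that
deviate from it, the per-cycle segmentation table (plain means,
`ensemble = FALSE`) remains the model-free reference. The relaxation
end additionally uses the across-cycle mean of the per-cycle
peak-to-maximum-diameter lag whenever a bell series is present, since
the bell series is not differentiated and its boundary is already tight.

For noisy digitizations we recommend (and use throughout the tests)
coordinate smoothing over ~1/10 of the pulse period before
differentiation, followed by resampling to ~40 samples per cycle — the
digitization-at-minimal-body-movement practice expressed as parameters.
Both choices are recorded in the output metadata.

## The synthetic pulsed swimmer

The generator is the package's ground truth. Within each cycle the speed
follows piecewise raised-cosine ramps: up from `trough_velocity` to
`peak_velocity` over the contraction fraction, back down over the
relaxation fraction, and a recapture bump of amplitude
`interpulse_gain * peak_velocity` during the interpulse. Raised cosines
are smooth, differentiable and have unambiguous extrema, so segmentation
tests are not confounded by spurious peaks. Bell kinematics are driven by
a prescribed fineness trajectory between `fineness_relaxed` and
`fineness_contracted` in antiphase with speed; bell height is held
constant so that $D(t) = h/f(t)$ and fineness recomputation from the
written series is exact. Positions are the cumulative trapezoid of the
analytic speed along a straight heading (real animals turn; straight
paths make the displacement decomposition exact for testing), plus
optional Gaussian jitter emulating digitization error. Closed-form phase
times, distances and PER come from `swimmer_truth()`.

Defaults describe a mid-sized medusa: 1 Hz, phase fractions
0.25/0.35/0.40 (contraction faster than relaxation, long coast), peak
4 cm s⁻¹, trough 0.5 cm s⁻¹, recapture gain 0.3 — giving PER ≈ 0.25,
the order of the largest recapture contributions reported for
*Aurelia*-like swimmers. The magnitude of the recapture bump is not
fixed by published profiles and remains a free parameter.

What the generator does *not* emulate: turning and body reorientation,
cycle-to-cycle period variability, non-Gaussian digitization error,
vortex hydrodynamics, and bell-margin kinematics. Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
measurement model, not performance on every real recording.

## Ontogenetic scaling and size normalization

Trait-versus-diameter scaling is fit by least squares in four
transformed spaces — linear, log-linear ($y \sim \log x$), power
($\log y \sim \log x$) and exponential ($\log y \sim x$) — spanning the
monotone shapes seen in ontogenetic series. Model choice is by BIC, made
comparable across response transforms by adding the log-Jacobian
($2\sum \log y$) to the log-response models' BIC, i.e. all models are
scored as densities for the *original* response. Shapiro–Wilk checks
(`check_normality()`) support the conventional log-transform decision.

The allometric correction removes size dependence by fitting the pooled
(all-species) BIC-best model and averaging residuals per species in the
fitted model's transformed space. When the pooled slope is not
significant (p > 0.05) there is no trend to remove, and residuals reduce
to centered trait values — the intercept-only special case. Species
means are unweighted. Group-wise fits (orders/families as co-factors)
with 95% confidence bands use the same machinery per group; groups with
fewer than four points are omitted with a warning.

## Ordination and phylogenetic comparative analysis

Pearson screening uses pairwise deletion with two-sided p-values from
the $t$ transform with $n-2$ df. PCA is an eigendecomposition of the
correlation matrix by default, because the traits mix units (s, cm, Hz,
dimensionless); covariance-matrix PCA is a flag. Component signs follow
a deterministic convention (largest-magnitude loading positive), scores
are the standardized data projected on the eigenvectors, and
rank-deficient tables simply carry trailing zero variances.

Blomberg's K is computed from the phylogenetic variance–covariance
matrix $C$ (shared root-to-MRCA path lengths, via `ape`):
$\hat a = (1'C^{-1}x)/(1'C^{-1}1)$,
$K = \frac{\mathrm{MSE}_0/\mathrm{MSE}}
          {(\mathrm{tr}(C) - n/1'C^{-1}1)/(n-1)}$
with $\mathrm{MSE}_0$ the ordinary and $\mathrm{MSE}$ the
$C^{-1}$-weighted mean squared deviation from $\hat a$. $K \approx 1$ is
the Brownian expectation on any tree; the randomization test shuffles
trait values across tips and uses the add-one p-value estimator
$(1 + \#\{K_{perm} \ge K_{obs}\})/(n_{perm}+1)$, so p is never 0.
Permutation count defaults to 1000 with a mandatory seed. Dense linear
algebra is used throughout: comparative datasets here are tens of taxa,
where factorizing $C$ once per tree is microseconds.

Ancestral states under Brownian motion are the joint ML estimates: the
node values minimizing $\sum_e (x_{child} - x_{parent})^2 / b_e$, found
by solving the branch-length-weighted tree Laplacian system. Each node's
estimate equals the re-rooted phylogenetically weighted mean, and the
root equals $\hat a$. States are interpolated linearly along edges at a
configurable grid (default 10 points/edge) for continuous trait maps — a
piecewise-linear approximation to finer along-edge interpolation.
Non-ultrametric trees are accepted throughout; zero-length branches are
replaced by $10^{-8}$ of tree depth (with a warning) so $C$ stays
invertible. Tip matching is exact string matching after whitespace
normalization.

The packaged 17-taxon tree (`scyphozoa_tree_synthetic()`) is a synthetic
stand-in: published topology motifs with invented branch lengths, for
calibration studies and worked examples — not a reconstruction.

## Pipeline and reproducibility

`run_pipeline()` executes trajectories → kinematics → segmentation →
per-sequence metrics → scaling fits → normalized species table →
correlations/PCA → phylogenetic signal and ancestral states, writing
plain CSV/TSV with unit-suffixed columns, a YAML config echo, a
diagnostics log (cycles detected, segmentation fallbacks) and an MD5
manifest. All randomness derives from the config seed; reruns are
bit-identical, and a run restarted from the cached per-sequence metrics
reproduces all downstream outputs exactly. Stage failures halt with a
stage-tagged error and preserve completed outputs.

## Problem sizes used in the checks

The test suite exercises: 27 generator configurations (3 pulse
frequencies × 3 contraction fractions × 3 recapture gains), clean at 6
cycles and jittered at 16 cycles per sequence with ~200 samples per
cycle; 100 random swimmer parameterizations for the partition
identities; 1000 Brownian replicates on the 17-taxon tree and 500 null
datasets (199 permutations each) for K calibration; 100 random trees of
up to 10 tips against independent oracles; and 100 simulated ontogenetic
datasets of n = 200 for model selection. These sizes make the
Monte-Carlo standard errors comfortably smaller than the tolerances
they are checked against.

## Known limitations

* The ensemble template assumes an approximately periodic gait; strongly
  arrhythmic swimming should be summarized from the per-cycle table.
* Folding velocity components assumes limited turning within a cycle;
  sustained sharp turns would bias folded speeds low.
* PER requires a resolvable interpulse; at high pulse rates without
  pauses (small ephyrae) the interpulse collapses and PER ≈ 0 by
  construction, matching the biology but leaving the phase boundary
  poorly identified.
* The allometric correction assumes one pooled scaling per trait;
  lineage-specific scaling shows up only in the group-wise fits, not in
  the normalization.
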