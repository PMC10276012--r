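# pulsekin

Swimming in scyphozoan jellyfish is a pulsed gait: the bell contracts
(thrust), relaxes (refill by elastic recoil), and then coasts through an
interpulse in which the stopping vortex pushes the animal forward for
free — *passive energy recapture* (PER). How these phases scale with
body size, and whether they carry phylogenetic signal across the
scyphozoan tree, are quantitative questions that start from digitized
video trajectories.

`pulsekin` is an R package for that analysis chain:

* **Kinematics** — instantaneous bell fineness (*f* = h/D), Pythagorean
  displacement, velocity, and Reynolds number (*Re* = D·u/ν, with a
  temperature-dependent seawater viscosity table) from apex
  trajectories.
* **Pulse segmentation** — prominence-based pulse detection, splitting of
  each cycle into contraction / relaxation / interpulse, and
  per-sequence metrics: pulsation frequency and time, per-pulse
  distance, phase times and distances, PER = mean interpulse distance /
  mean cycle displacement, and per-pulse velocity and *Re* maxima. Noisy
  digitizations are summarized from an ensemble-averaged (peak-folded)
  cycle with template-based boundary refinement.
* **Ontogenetic scaling** — BIC-selected regression families (linear,
  log-linear, power, exponential; BICs made comparable across response
  transforms), group-wise fits with 95% bands, and allometric size
  normalization via pooled-regression residual means per species.
* **Multivariate** — Pearson correlation screening and correlation-matrix
  PCA of the size-normalized species trait table.
* **Phylogenetic comparative analysis** — Blomberg's K with a
  randomization test, and maximum-likelihood ancestral states under
  Brownian motion with along-edge interpolation, on a user-supplied
  Newick tree (pruned to the trait species).
* **Synthetic ground truth** — a pulsed-swimmer generator with
  raised-cosine phase profiles and closed-form phase times/distances, a
  power-law ontogenetic dataset generator, and Brownian-motion trait
  simulation on trees, so every stage is testable without video data.

## Worked example

```r
library(pulsekin)

## a 4 cm medusa pulsing at 1.2 Hz with a long interpulse coast
p  <- swimmer_params(pulse_freq = 1.2, bell_diameter_relaxed = 4)
tr <- simulate_swimmer(p, duration = 6, dt = 0.005)
a  <- analyze_sequence(tr)
round(unlist(a$metrics[c("n_pulses", "P_freq", "P_time", "C_time", "R_time",
                         "I_time", "PER", "u_mean", "Re_mean", "f_mean")]), 3)
#> n_pulses   P_freq   P_time   C_time   R_time   I_time      PER   u_mean
#>    5.000    1.200    0.834    0.208    0.292    0.333    0.245    1.791
#>  Re_mean   f_mean
#>  507.269    0.621
```

Five complete pulses were detected; the recovered pulsation frequency
(1.2 Hz), phase times (0.208/0.292/0.333 s) and PER (0.245) match the
generator's closed-form truth (0.208/0.292/0.333 s, PER 0.246): about a
quarter of each cycle's travel happens during the passive coast. The
mean Reynolds number (~507) puts this animal in the inertia-dominated
regime.

Phylogenetic signal of a Brownian trait on the packaged 17-taxon
synthetic scyphozoan tree:

```r
tree <- scyphozoa_tree_synthetic()
x    <- simulate_bm_traits(tree, sigma2 = 1, seed = 99)
blomberg_k_test(tree, x, n_perm = 999, seed = 7)
#> <k_result> K = 1.601, p = 0.0010 (999 permutations, seed 7)
```

`run_pipeline(pipeline_config(...))` chains every stage — per-sequence
metrics, scaling fits, the size-normalized species table, correlations,
PCA, K per trait, and ancestral-state maps — into one output directory
with a config echo, per-sequence diagnostics log, and an MD5 manifest;
reruns with the same seed are bit-identical.

See the methods vignette (`vignettes/pulsekin-methods.Rmd`) for the
models, detection rules, and design decisions.

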