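## Evaluate expr under a temporary RNG state.
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

## Random valid swimmer parameters within the regimes the generator is
## meant to emulate (ephyra-to-medusa pulsing, modest recapture bump).
random_swimmer_params <- function() {
  fc <- runif(1, 0.2, 0.35)
  fi <- runif(1, 0.1, 0.45)
  peak <- runif(1, 2, 6)
  swimmer_params(pulse_freq = runif(1, 0.8, 3),
                 frac_contraction = fc,
                 frac_relaxation = 1 - fc - fi,
                 frac_interpulse = fi,
                 peak_velocity = peak,
                 trough_velocity = runif(1, 0.05, 0.15) * peak,
                 interpulse_gain = runif(1, 0, 0.4),
                 bell_diameter_relaxed = runif(1, 0.5, 8),
                 fineness_relaxed = runif(1, 0.35, 0.55),
                 fineness_contracted = runif(1, 0.7, 1.1),
                 heading = runif(1, -pi, pi))
}

## Deep balanced 16-tip tree: long internal edges, short tip edges, so
## phylogenetic clustering dominates tip-level variation.
deep_balanced_tree <- function(n = 16, internal = 1, tip = 0.05) {
  tree <- ape::stree(n, type = "balanced")
  tree$edge.length <- ifelse(tree$edge[, 2] <= n, tip, internal)
  tree
}

## Analysis settings used for noisy synthetic sequences: position smoothing
## before differentiation, then resampling to ~40 samples per cycle (the
## "minimal body movement" digitization interval).
analyze_noisy <- function(traj, period) {
  analyze_sequence(traj, smooth_window = 21, resample_dt = period / 40)
}
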