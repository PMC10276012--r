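#' Generate an ontogenetic trait dataset with power-law ground truth
#'
#' Draws trait values from species-specific allometric power laws
#' `trait = a * D^b * exp(eps)`, `eps ~ Normal(0, sd^2)`, over a set of bell
#' diameters.  Used to exercise the scaling-model selection and allometric
#' normalization stages with known truth.
#'
#' @param species_specs named list (one element per species).  Each element
#'   is a named list of traits, each trait a numeric vector
#'   `c(a = intercept, b = exponent, sd = lognormal noise sd)`.
#' @param diameters bell diameters (cm): either a numeric vector applied to
#'   every species or a named list of per-species vectors.
#' @param seed integer seed.
#' @return data.frame with columns `species`, `diameter_cm`, and one column
#'   per trait.
#' @examples
#' specs <- list(A = list(u_mean = c(a = 1, b = 0.8, sd = 0.1)))
#' generate_ontogenetic_dataset(specs, diameters = c(1, 2, 4), seed = 1)
#' @export
generate_ontogenetic_dataset <- function(species_specs, diameters, seed = 1) {
  if (!is.list(species_specs) || is.null(names(species_specs)) ||
      any(names(species_specs) == ""))
    stop_invalid("'species_specs' must be a named list of species")
  if (is.numeric(diameters)) {
    diameters <- stats::setNames(rep(list(diameters), length(species_specs)),
                                 names(species_specs))
  }
  if (any(vapply(diameters, length, 1L) == 0L))
    stop_invalid("empty diameter list")
  if (any(unlist(diameters) <= 0)) stop_invalid("diameters must be > 0")
  trait_names <- unique(unlist(lapply(species_specs, names)))
  with_seed(seed, {
    rows <- lapply(names(species_specs), function(sp) {
      D <- diameters[[sp]]
      df <- data.frame(species = sp, diameter_cm = D)
      for (tr in trait_names) {
        spec <- species_specs[[sp]][[tr]]
        if (is.null(spec)) {
          df[[tr]] <- NA_real_
        } else {
          a <- spec[["a"]]; b <- spec[["b"]]; sd <- spec[["sd"]]
          eps <- if (sd > 0) stats::rnorm(length(D), 0, sd) else 0
          df[[tr]] <- a * D^b * exp(eps)
        }
      }
      df
    })
    do.call(rbind, rows)
  })
}

#' Simulate continuous traits under Brownian motion on a tree
#'
#' Tip values are drawn from a multivariate normal with mean `root_state`
#' and covariance `sigma2 * C`, where `C` is the shared-path-length
#' (phylogenetic variance-covariance) matrix of the tree.
#'
#' @param tree a rooted `phylo` tree with positive branch lengths.
#' @param sigma2 Brownian rate (trait^2 per branch-length unit), >= 0.
#' @param root_state trait value at the root.
#' @param seed integer seed (optional).
#' @param nsim number of independent replicates.
#' @return For `nsim = 1` a named numeric vector over tips; otherwise a
#'   tips x `nsim` matrix.
#' @export
simulate_bm_traits <- function(tree, sigma2, root_state = 0, seed = NULL, nsim = 1) {
  tree <- as_phylo_checked(tree, need_lengths = TRUE)
  if (any(tree$edge.length <= 0))
    stop_invalid("branch lengths must be positive for Brownian simulation")
  assert_scalar_num(sigma2, "sigma2", nonneg = TRUE)
  assert_scalar_num(root_state, "root_state")
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    out <- matrix(root_state, n, nsim, dimnames = list(tree$tip.label, NULL))
  } else {
    C <- phylo_vcv(tree)
    U <- chol(C)  # C = t(U) %*% U
    Z <- with_seed(seed, matrix(stats::rnorm(n * nsim), n, nsim))
    out <- root_state + sqrt(sigma2) * crossprod(U, Z)
    dimnames(out) <- list(tree$tip.label, NULL)
  }
  if (nsim == 1L) out[, 1L] else out
}

#' Synthetic multi-species swimming study
#'
#' Builds a small end-to-end test bed: several species, each recorded at
#' several bell diameters, with swimmer parameters scaling allometrically
#' with size (pulsation frequency declining, speed increasing) and two
#' kinematic syndromes -- fast pulsers with short interpulses versus slow
#' pulsers with long interpulse coasts -- plus a five-taxon tree linking
#' the species.
#'
#' @param n_species number of species (2..8).
#' @param diameters bell diameters (cm) at which each species is recorded.
#' @param duration,dt recording length and sampling interval (s).
#' @param noise_sd positional jitter sd (cm).
#' @param seed integer seed.
#' @return list with `trajectories` (named list of [trajectory()]),
#'   `params` (matching [swimmer_params()]), `meta` (data.frame of species,
#'   individual, diameter), and `tree` (a `phylo` over the species).
#' @export
make_demo_dataset <- function(n_species = 5, diameters = c(0.5, 2, 6),
                              duration = NULL, dt = NULL, noise_sd = 0,
                              seed = 1) {
  if (n_species < 2 || n_species > 8) stop_invalid("n_species must be in 2..8")
  species <- paste0("sp", seq_len(n_species))
  ## alternate kinematic syndromes -- odd species fast/short-interpulse,
  ## even species slow/long-interpulse -- plus lognormal species effects so
  ## species within a syndrome still differ
  eff <- with_seed(seed, matrix(exp(stats::rnorm(3L * n_species, 0, 0.12)),
                                nrow = n_species))
  trajectories <- list()
  params_list <- list()
  meta <- NULL
  k <- 0L
  for (i in seq_len(n_species)) {
    fast <- i %% 2L == 1L
    for (D in diameters) {
      k <- k + 1L
      freq <- (if (fast) 2.4 else 1.6) * eff[i, 1L] * D^-0.35
      peak <- (if (fast) 2.2 else 1.6) * eff[i, 2L] * D^0.55
      fi <- min(0.55, (if (fast) 0.25 else 0.40) * eff[i, 3L])
      fc <- (1 - fi) * 0.4
      p <- swimmer_params(
        pulse_freq = freq,
        frac_contraction = fc,
        frac_relaxation = 1 - fi - fc,
        frac_interpulse = fi,
        peak_velocity = peak,
        trough_velocity = 0.1 * peak,
        interpulse_gain = if (fast) 0.15 else 0.35,
        bell_diameter_relaxed = D,
        fineness_relaxed = (if (fast) 0.55 else 0.40) * sqrt(eff[i, 1L]),
        fineness_contracted = (if (fast) 0.95 else 0.80) * sqrt(eff[i, 1L]),
        noise_sd = noise_sd,
        species = species[i],
        individual = sprintf("ind%02d", k))
      dur <- duration %||% max(4 / freq, 3)
      step <- dt %||% (1 / (100 * freq))
      id <- sprintf("%s_D%.2g", species[i], D)
      trajectories[[id]] <- simulate_swimmer(p, dur, step, seed = seed + k)
      params_list[[id]] <- p
      meta <- rbind(meta, data.frame(id = id, species = species[i],
                                     individual = p$individual, diameter_cm = D))
    }
  }
  tree <- ape::read.tree(text = demo_tree_newick(species))
  list(trajectories = trajectories, params = params_list, meta = meta, tree = tree)
}

## ladder tree over the requested species, unit-ish branch lengths
demo_tree_newick <- function(species) {
  n <- length(species)
  txt <- sprintf("%s:1", species[1])
  for (i in 2:n) txt <- sprintf("(%s,%s:%g):0.5", txt, species[i], i * 0.8)
  paste0(sub(":0.5$", "", txt), ";")
}
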