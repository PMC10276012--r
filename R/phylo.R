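## Validate/normalize a phylo object.
as_phylo_checked <- function(tree, need_lengths = TRUE) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (!inherits(tree, "phylo")) stop_invalid("'tree' must be a phylo object or Newick")
  if (length(tree$tip.label) < 2L) stop_invalid("tree needs at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop_invalid("duplicate tip labels")
  if (need_lengths) {
    if (is.null(tree$edge.length) || anyNA(tree$edge.length))
      stop_invalid("tree must have branch lengths on every edge")
    if (any(tree$edge.length < 0)) stop_invalid("negative branch lengths")
  }
  tree
}

#' Read and write Newick trees
#'
#' Thin wrappers around `ape::read.tree()` / `ape::write.tree()` adding the
#' validation the comparative analyses rely on: unique tip labels and
#' branch lengths on every edge (unless a `default_length` is supplied for
#' cladogram inputs).  `read_newick()` accepts a file path or a literal
#' Newick string.
#'
#' @param source file path or Newick text.
#' @param default_length optional branch length substituted when the input
#'   has none.
#' @return `read_newick()`: a `phylo`; `write_newick()`: the path,
#'   invisibly.
#' @export
read_newick <- function(source, default_length = NULL) {
  tree <- if (grepl("\\(", source)) ape::read.tree(text = source)
          else ape::read.tree(file = source)
  if (is.null(tree)) stop_invalid("could not parse Newick input")
  if (anyDuplicated(tree$tip.label)) stop_invalid("duplicate tip labels")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (is.null(default_length))
      stop_invalid("Newick input lacks branch lengths (set default_length to override)")
    el <- tree$edge.length
    if (is.null(el)) el <- rep(NA_real_, nrow(tree$edge))
    el[is.na(el)] <- default_length
    tree$edge.length <- el
  }
  tree
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo_checked(tree), file = path)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Induced subtree on `taxa`: dropped degree-2 internal nodes are
#' suppressed with their branch lengths summed, so patristic distances
#' among the retained tips are unchanged (the 148-to-17-terminal style of
#' reduction used when trait data cover fewer species than the tree).
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip labels to retain (>= 2).
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  tree <- as_phylo_checked(tree, need_lengths = FALSE)
  missing_taxa <- setdiff(taxa, tree$tip.label)
  if (length(missing_taxa))
    stop_invalid("taxa not in tree: ", paste(missing_taxa, collapse = ", "))
  if (length(taxa) < 2L) stop_invalid("need at least 2 taxa")
  ape::keep.tip(tree, taxa)
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j (the
#' Brownian-motion covariance structure); the diagonal holds root-to-tip
#' depths.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric positive semidefinite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree) {
  tree <- as_phylo_checked(tree)
  ape::vcv.phylo(tree)
}

## Replace non-positive branch lengths so C is invertible.
fix_zero_branches <- function(tree) {
  if (any(tree$edge.length <= 0)) {
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    warning("replacing ", sum(tree$edge.length <= 0),
            " non-positive branch length(s) by ", format(eps))
    tree$edge.length[tree$edge.length <= 0] <- eps
  }
  tree
}

## Match a named trait vector to tree tips; errors on mismatch.
match_traits <- function(tree, traits) {
  if (is.null(names(traits))) {
    if (length(traits) != length(tree$tip.label))
      stop_invalid("unnamed trait vector must match the number of tips")
    names(traits) <- tree$tip.label
    return(traits)
  }
  names(traits) <- trimws(names(traits))
  missing_tips <- setdiff(tree$tip.label, names(traits))
  if (length(missing_tips))
    stop_invalid("traits missing for tips: ", paste(missing_tips, collapse = ", "))
  traits[tree$tip.label]
}

## Precompute everything needed to evaluate K for many trait vectors on one
## tree (the randomization test evaluates thousands).
k_stat_closure <- function(tree) {
  C <- phylo_vcv(tree)
  n <- nrow(C)
  invC <- chol2inv(chol(C))
  ones <- rep(1, n)
  invC_rowsum <- invC %*% ones
  sum_invC <- sum(invC_rowsum)
  expected_ratio <- (sum(diag(C)) - n / sum_invC) / (n - 1)
  function(x) {
    ahat <- sum(invC_rowsum * x) / sum_invC
    d <- x - ahat
    mse0 <- sum(d * d)
    mse <- drop(crossprod(d, invC %*% d))
    (mse0 / mse) / expected_ratio
  }
}

#' Blomberg's K phylogenetic signal
#'
#' The variance-ratio statistic of Blomberg et al.: with the phylogenetic
#' mean `a = (1' C^-1 x) / (1' C^-1 1)`,
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`, where
#' `MSE0 = (x - a)'(x - a) / (n - 1)`,
#' `MSE = (x - a)' C^-1 (x - a) / (n - 1)` and
#' `E[MSE0 / MSE] = (tr(C) - n / (1' C^-1 1)) / (n - 1)`.
#' K is about 1 when trait similarity matches Brownian motion on the tree,
#' approaches 0 for phylogeny-independent traits, and exceeds 1 when
#' relatives are even more similar than Brownian motion predicts.  K is
#' invariant to affine trait transforms and to rescaling all branch
#' lengths.
#'
#' @param tree a rooted `phylo` with branch lengths (non-positive lengths
#'   are replaced by a tiny fraction of tree depth, with a warning).
#' @param traits named numeric vector over the tips (n >= 3,
#'   non-constant).
#' @return the K statistic (single positive number).
#' @export
blomberg_k <- function(tree, traits) {
  tree <- fix_zero_branches(as_phylo_checked(tree))
  x <- match_traits(tree, traits)
  if (length(x) < 3L) stop_invalid("need at least 3 tips")
  if (anyNA(x) || !all(is.finite(x))) stop_invalid("traits must be finite")
  if (stats::sd(x) == 0) stop_invalid("constant trait: K undefined")
  k_stat_closure(tree)(x)
}

#' Randomization test for Blomberg's K
#'
#' Null distribution from shuffling the trait values across the tips
#' (which destroys any phylogenetic structure while keeping the trait
#' distribution); the p-value uses the add-one estimator
#' `p = (1 + #[K_perm >= K_obs]) / (n_perm + 1)` so it can never be 0.
#'
#' @inheritParams blomberg_k
#' @param n_perm number of permutations (>= 99; default 1000).
#' @param seed integer seed (the permutations are the only randomness).
#' @return An object of class `"k_result"`: list with `K`, `p`, `n_perm`,
#'   `seed`, `K_perm`.
#' @export
blomberg_k_test <- function(tree, traits, n_perm = 1000, seed = 1) {
  if (n_perm < 99) stop_invalid("n_perm must be at least 99")
  tree <- fix_zero_branches(as_phylo_checked(tree))
  x <- match_traits(tree, traits)
  if (length(x) < 3L) stop_invalid("need at least 3 tips")
  if (stats::sd(x) == 0) stop_invalid("constant trait: K undefined")
  kfun <- k_stat_closure(tree)
  k_obs <- kfun(x)
  k_perm <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(i) kfun(sample(x)), numeric(1)))
  structure(list(K = k_obs,
                 p = (1 + sum(k_perm >= k_obs)) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = seed, K_perm = k_perm),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("<k_result> K = %.3f, p = %.4f (%d permutations, seed %s)\n",
              x$K, x$p, x$n_perm, format(x$seed)))
  invisible(x)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML estimates of the internal-node states: the values minimizing
#' the Brownian sum of squares `sum((x_child - x_parent)^2 / b_edge)`,
#' obtained by solving the branch-length-weighted tree Laplacian system.
#' Each node's estimate equals the re-rooted phylogenetically weighted
#' (GLS) mean, and the root estimate equals the phylogenetic mean
#' `(1' C^-1 x) / (1' C^-1 1)`.  States are interpolated linearly along
#' each edge at a user grid for continuous trait maps.
#'
#' @inheritParams blomberg_k
#' @param grid_points interpolation points per edge (default 10).
#' @return An object of class `"ancestral_map"`: list with `node_states`
#'   (named by node number, root first), `tip_states`, `edge_grid`
#'   (data.frame `edge`, `parent`, `child`, `frac`, `time`, `state`), and
#'   `tree`.
#' @export
ancestral_states_ml <- function(tree, traits, grid_points = 10) {
  tree <- fix_zero_branches(as_phylo_checked(tree))
  x <- match_traits(tree, traits)
  if (anyNA(x) || !all(is.finite(x))) stop_invalid("traits must be finite")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  ## branch-length-weighted graph Laplacian over all nodes
  L <- matrix(0, ntot, ntot)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    w <- 1 / tree$edge.length[e]
    L[a, a] <- L[a, a] + w; L[b, b] <- L[b, b] + w
    L[a, b] <- L[a, b] - w; L[b, a] <- L[b, a] - w
  }
  internal <- (ntip + 1L):ntot
  states <- drop(solve(L[internal, internal, drop = FALSE],
                       -L[internal, seq_len(ntip), drop = FALSE] %*% x))
  names(states) <- as.character(internal)
  all_states <- c(x, states)
  frac <- seq(0, 1, length.out = grid_points + 1L)
  grids <- lapply(seq_len(nrow(tree$edge)), function(e) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    data.frame(edge = e, parent = a, child = b, frac = frac,
               time = frac * tree$edge.length[e],
               state = all_states[a] + frac * (all_states[b] - all_states[a]))
  })
  structure(list(node_states = states, tip_states = x,
                 edge_grid = do.call(rbind, grids), tree = tree),
            class = "ancestral_map")
}

#' @export
print.ancestral_map <- function(x, ...) {
  cat(sprintf("<ancestral_map> %d internal nodes; root state = %.4g\n",
              length(x$node_states), x$node_states[1]))
  invisible(x)
}

#' Synthetic 17-taxon scyphozoan tree
#'
#' A stand-in phylogeny over the 17 species whose swimming has been
#' characterized (1 coronate, 8 "semaeostomes", 8 rhizostomes): the
#' published topology motifs -- Pelagiidae early-branching within
#' Discomedusae, Rhizostomeae monophyletic and sister to Ulmaridae -- with
#' *invented* branch lengths.  It is synthetic: useful for calibration
#' studies (the expectation of Blomberg's K under Brownian motion is ~1 on
#' any tree) and as a worked-example input, not a reconstruction.
#'
#' @return a 17-tip `phylo`.
#' @export
scyphozoa_tree_synthetic <- function() {
  read_newick(system.file("extdata", "scyphozoa_17taxa_synthetic.nwk",
                          package = "pulsekin", mustWork = TRUE))
}

#' Phylogenetic signal across a trait table
#'
#' [blomberg_k_test()] for each column of a size-normalized species trait
#' table, matched to the tree tips (the tree is pruned to the table's
#' species first when it is larger).
#'
#' @param tree a `phylo`.
#' @param trait_table data.frame/matrix with species rownames and one
#'   column per trait.
#' @param n_perm,seed passed to [blomberg_k_test()] (each trait uses an
#'   offset seed for independence).
#' @return data.frame `variable`, `K`, `p`, `n_tips`, sorted by
#'   decreasing K.
#' @export
phylo_signal_table <- function(tree, trait_table, n_perm = 1000, seed = 1) {
  tree <- as_phylo_checked(tree)
  sp <- rownames(trait_table)
  if (is.null(sp)) stop_invalid("trait table must have species rownames")
  common <- intersect(tree$tip.label, sp)
  if (length(common) < 3L) stop_invalid("fewer than 3 species shared with the tree")
  if (length(common) < length(tree$tip.label)) tree <- prune_to_taxa(tree, common)
  rows <- lapply(seq_len(ncol(trait_table)), function(j) {
    x <- stats::setNames(trait_table[common, j], common)
    ok <- !is.na(x)
    tr <- if (sum(ok) < length(common)) prune_to_taxa(tree, names(x)[ok]) else tree
    res <- blomberg_k_test(tr, x[ok], n_perm = n_perm, seed = seed + j)
    data.frame(variable = colnames(trait_table)[j], K = res$K, p = res$p,
               n_tips = sum(ok))
  })
  out <- do.call(rbind, rows)
  out[order(-out$K), , drop = FALSE]
}
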