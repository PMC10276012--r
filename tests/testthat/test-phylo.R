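test_that("Newick parsing validates and round-trips", {
  t2 <- read_newick("(A:1,B:1);")
  expect_identical(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(1, 1))
  t3 <- read_newick("((A:1,B:1):0.5,C:1.5);")
  d <- cophenetic(t3)
  expect_equal(d["A", "C"], 3)
  expect_error(read_newick("(A:1,B;"), "parse|Newick")
  expect_error(read_newick("(A:1,A:1);"), "duplicate")
  expect_error(read_newick("(A,B);"), "branch lengths")
  expect_equal(read_newick("(A,B);", default_length = 1)$edge.length, c(1, 1))
  path <- tempfile(fileext = ".nwk")
  write_newick(t3, path)
  back <- read_newick(path)
  expect_equal(cophenetic(back)[rownames(d), colnames(d)], d, tolerance = 1e-12)
})

test_that("pruning preserves patristic distances among retained tips", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  pruned <- prune_to_taxa(tr, c("A", "C"))
  expect_identical(sort(pruned$tip.label), c("A", "C"))
  expect_equal(sum(pruned$edge.length), 4)  # (A:2,C:2)
  expect_equal(cophenetic(pruned)["A", "C"], 4)
  full <- prune_to_taxa(tr, tr$tip.label)
  expect_equal(cophenetic(full), cophenetic(tr), tolerance = 1e-12)
  expect_error(prune_to_taxa(tr, c("A", "X")), "X")
  for (s in 1:20) {
    big <- with_seed_local(s, ape::rtree(12))
    keep <- with_seed_local(100 + s, sample(big$tip.label, 6))
    sub <- prune_to_taxa(big, keep)
    expect_equal(cophenetic(sub)[keep, keep], cophenetic(big)[keep, keep],
                 tolerance = 1e-9)
  }
})

test_that("the phylogenetic covariance matrix is the shared-path matrix", {
  expect_equal(phylo_vcv(read_newick("(A:1,B:1);")),
               diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  C <- phylo_vcv(read_newick("((A:1,B:1):0.5,C:1.5);"))
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "A"], 1.5)
  expect_equal(C["A", "C"], 0)
  for (s in 1:100) {
    tr <- with_seed_local(200 + s, ape::rtree(8))
    Cr <- phylo_vcv(tr)
    expect_true(isSymmetric(Cr, tol = 1e-12))
    expect_gte(min(eigen(Cr, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("Blomberg's K matches phylosig and honors its invariances", {
  tree <- scyphozoa_tree_synthetic()
  expect_identical(length(tree$tip.label), 17L)
  x <- simulate_bm_traits(tree, sigma2 = 1, seed = 42)
  k <- blomberg_k(tree, x)
  expect_equal(k, as.numeric(phytools::phylosig(tree, x)), tolerance = 1e-8)
  ## affine trait transforms and branch-length rescaling leave K unchanged
  expect_equal(blomberg_k(tree, 3 * x - 7), k, tolerance = 1e-10)
  scaled <- tree
  scaled$edge.length <- tree$edge.length * 4.2
  expect_equal(blomberg_k(scaled, x), k, tolerance = 1e-10)
  ## tip order in the trait vector must not matter
  expect_equal(blomberg_k(tree, x[rev(names(x))]), k, tolerance = 1e-12)
  expect_error(blomberg_k(tree, x[-1]), "missing")
  expect_error(blomberg_k(tree, setNames(rep(1, 17), names(x))), "constant")
})

test_that("K is ~1 under Brownian motion and small for white noise", {
  tree <- scyphozoa_tree_synthetic()
  sims <- simulate_bm_traits(tree, sigma2 = 1, seed = 7, nsim = 300)
  kfun <- pulsekin:::k_stat_closure(tree)
  k_bm <- apply(sims, 2, kfun)
  expect_gt(mean(k_bm), 0.85)
  expect_lt(mean(k_bm), 1.15)
  deep <- deep_balanced_tree()
  kfun_d <- pulsekin:::k_stat_closure(deep)
  k_wn <- vapply(1:300, function(s)
    kfun_d(with_seed_local(500 + s, rnorm(16))), numeric(1))
  expect_lt(mean(k_wn), 0.5)
})

test_that("the randomization test is deterministic, calibrated and powerful", {
  tree <- scyphozoa_tree_synthetic()
  x <- simulate_bm_traits(tree, sigma2 = 1, seed = 9)
  r1 <- blomberg_k_test(tree, x, n_perm = 199, seed = 3)
  r2 <- blomberg_k_test(tree, x, n_perm = 199, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)
  expect_error(blomberg_k_test(tree, x, n_perm = 50), "99")
  ## power: strong Brownian signal on a deep tree is usually detected
  deep <- deep_balanced_tree()
  hits <- sum(vapply(1:40, function(s) {
    y <- simulate_bm_traits(deep, sigma2 = 1, seed = 700 + s)
    blomberg_k_test(deep, y, n_perm = 199, seed = s)$p <= 0.05
  }, logical(1)))
  expect_gte(hits, 32)  # >= 80%
})

test_that("ancestral states reproduce closed forms and the GLS root", {
  t2 <- read_newick("(A:1,B:1);")
  am <- ancestral_states_ml(t2, c(A = 0, B = 2))
  expect_equal(unname(am$node_states[1]), 1, tolerance = 1e-10)
  t24 <- read_newick("(A:1,B:3);")
  am2 <- ancestral_states_ml(t24, c(A = 0, B = 4))
  expect_equal(unname(am2$node_states[1]), 1, tolerance = 1e-10)  # (0/1+4/3)/(1+1/3)
  tc <- read_newick("((A:1,B:1):0.5,C:1.5);")
  amc <- ancestral_states_ml(tc, c(A = 5, B = 5, C = 5))
  expect_true(all(abs(amc$node_states - 5) < 1e-10))
})

test_that("ancestral estimates agree with the re-rooted GLS oracle on random trees", {
  for (s in 1:100) {
    n <- with_seed_local(s, sample(4:10, 1))
    tr <- with_seed_local(1000 + s, ape::rtree(n))
    x <- with_seed_local(2000 + s, setNames(rnorm(n), tr$tip.label))
    am <- ancestral_states_ml(tr, x)
    ## root state equals the GLS phylogenetic mean computed from C
    C <- phylo_vcv(tr)
    invC <- solve(C)
    ahat <- sum(invC %*% x[rownames(C)]) / sum(invC)
    expect_equal(unname(am$node_states[1]), ahat, tolerance = 1e-8)
    if (s <= 30) {  # full-node oracle via phytools
      fa <- phytools::fastAnc(tr, x)
      expect_equal(unname(am$node_states[names(fa)]), unname(fa),
                   tolerance = 1e-8)
    }
  }
})

test_that("edge interpolation hits the node states and shifts with the tips", {
  tree <- with_seed_local(8, ape::rtree(6))
  x <- with_seed_local(9, setNames(rnorm(6), tree$tip.label))
  am <- ancestral_states_ml(tree, x, grid_points = 10)
  all_states <- c(x[tree$tip.label], am$node_states)
  for (e in seq_len(nrow(tree$edge))) {
    g <- am$edge_grid[am$edge_grid$edge == e, ]
    expect_equal(g$state[1], unname(all_states[g$parent[1]]), tolerance = 1e-12)
    expect_equal(g$state[nrow(g)], unname(all_states[g$child[1]]), tolerance = 1e-12)
  }
  shifted <- ancestral_states_ml(tree, x + 11)
  expect_equal(shifted$node_states, am$node_states + 11, tolerance = 1e-9)
})

test_that("zero-length branches are repaired with a warning", {
  tr <- read_newick("((A:1,B:0):1,C:2);")
  x <- c(A = 1, B = 2, C = 0)
  expect_warning(k <- blomberg_k(tr, x), "non-positive")
  expect_true(is.finite(k))
})

test_that("the signal table prunes, orders and labels traits", {
  tree <- scyphozoa_tree_synthetic()
  tab <- as.data.frame(simulate_bm_traits(tree, 1, seed = 12, nsim = 3))
  colnames(tab) <- c("u_mean", "P_freq", "PER")
  res <- phylo_signal_table(tree, tab, n_perm = 199, seed = 5)
  expect_identical(sort(res$variable), sort(colnames(tab)))
  expect_true(all(diff(res$K) <= 0))
  expect_true(all(res$p >= 1 / 200 & res$p <= 1))
  ## extra tree tips are pruned away
  res2 <- phylo_signal_table(tree, tab[1:10, , drop = FALSE],
                             n_perm = 199, seed = 5)
  expect_true(all(res2$n_tips == 10))
})
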