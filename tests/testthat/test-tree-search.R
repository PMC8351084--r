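test_that("topology enumeration matches (2n-5)!! and is duplicate-free", {
  expect_length(enumerate_unrooted_topologies(c("a", "b", "c", "d")), 3)
  expect_length(enumerate_unrooted_topologies(letters[1:5]), 15)
  t6 <- enumerate_unrooted_topologies(letters[1:6])
  expect_length(t6, 105)
  keys <- vapply(t6, canonical_newick, "")
  expect_false(anyDuplicated(keys) > 0)
  expect_error(enumerate_unrooted_topologies(letters[1:2]), "3..8")
  expect_error(enumerate_unrooted_topologies(letters[1:9]), "exhaustive")
})

test_that("canonical newick identifies identical unrooted topologies", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "(e,(d,c),(b,a));")
  t3 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_identical(canonical_newick(t1), canonical_newick(t2))
  expect_false(canonical_newick(t1) == canonical_newick(t3))
})

test_that("exhaustive 4-taxon search agrees with an independent ML oracle", {
  m <- subst_model("JC")
  for (seed in 1:4) {
    truth <- random_bl_tree("((a,b),(c,d));", seed = seed, lo = 0.05, hi = 0.4)
    aln <- simulate_alignment(simulation_spec(truth, m, 800, seed = seed))
    mine <- ml_tree_search(aln, m)
    # oracle: optimize each quartet with phangorn and compare rankings
    pd <- as_phyDat(aln)
    topos <- enumerate_unrooted_topologies(taxa(aln))
    lnl <- vapply(topos, function(tp) {
      tp$edge.length <- rep(0.1, nrow(tp$edge))
      phangorn::optim.pml(phangorn::pml(tp, pd), optEdge = TRUE,
                          control = phangorn::pml.control(trace = 0))$logLik
    }, 0)
    best_oracle <- canonical_newick(topos[[which.max(lnl)]])
    expect_identical(mine$table$topology[1], best_oracle)
    expect_equal(mine$table$logLik[1], max(lnl), tolerance = 1e-3)
  }
})

test_that("uninformative data still yields a strict deterministic ranking", {
  aln <- random_alignment(5, 10, "nt", seed = 30)
  m <- subst_model("JC")
  s1 <- ml_tree_search(aln, m)
  s2 <- ml_tree_search(aln, m)
  expect_identical(s1$table, s2$table)
  expect_equal(nrow(s1$table), 15L)
  expect_false(anyDuplicated(s1$table$topology) > 0)
  # ties broken by lexicographic canonical newick
  ties <- s1$table[abs(s1$table$logLik - s1$table$logLik[1]) < 1e-9, ]
  if (nrow(ties) > 1) expect_identical(ties$topology, sort(ties$topology))
})

test_that("identical strain tips form a cherry in every best tree", {
  for (seed in 1:10) {
    sc <- make_lba_scenario(lba_scenario_spec(
      strain_divergence = 0, n_sites = 300, seed = seed,
      model = subst_model("LG", frequencies = NULL)))
    s <- ml_tree_search(sc$ingroup_alignment, subst_model("LG"))
    expect_true(has_bipartition(s$best_tree, c("seison_A", "seison_B")))
  }
})

test_that("search recovers the generating 5-taxon topology", {
  truth <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1,e:0.1);")
  m <- subst_model("JC")
  hits <- vapply(1:10, function(s) {
    aln <- simulate_alignment(simulation_spec(truth, m, 2000, seed = s))
    ml_tree_search(aln, m)$table$topology[1] == canonical_newick(truth)
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("bootstrap supports are reproducible, bounded and sensible", {
  truth <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2,e:0.1);")
  m <- subst_model("JC")
  aln <- simulate_alignment(simulation_spec(truth, m, 1000, seed = 8))
  s <- ml_tree_search(aln, m)
  b1 <- bootstrap_support(aln, m, s$best_tree, B = 20, seed = 7)
  b2 <- bootstrap_support(aln, m, s$best_tree, B = 20, seed = 7)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 1))
  expect_gte(min(b1$support), 0.9)        # clean data, strong internals
  b3 <- bootstrap_support(aln, m, s$best_tree, B = 1, seed = 3)
  expect_true(all(b3$support %in% c(0, 1)))
  expect_error(bootstrap_support(aln, m, s$best_tree, B = 0), "B must be")
})

test_that("bootstrap supports are invariant to taxon input order", {
  truth <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2,e:0.1);")
  m <- subst_model("JC")
  aln <- simulate_alignment(simulation_spec(truth, m, 500, seed = 9))
  perm <- structure(list(seq = aln$seq[c(3, 1, 5, 2, 4), ], alphabet = "nt"),
                    class = "lca_alignment")
  s <- ml_tree_search(aln, m)
  b1 <- bootstrap_support(aln, m, s$best_tree, B = 10, seed = 5)
  b2 <- bootstrap_support(perm, m, s$best_tree, B = 10, seed = 5)
  expect_identical(b1$support[sort(names(b1$support))],
                   b2$support[sort(names(b2$support))])
})

test_that("rooting on a tip splits its pendant edge and round-trips", {
  tr <- random_bl_tree("((a,b),(c,d));", seed = 21, lo = 0.1, hi = 0.5)
  tru <- ape::unroot(tr)
  pend <- tru$edge.length[tru$edge[, 2] == match("d", tru$tip.label)]
  rooted <- root_with_taxon(tru, "d")
  root <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1] == root)
  expect_length(kids, 2)
  expect_true(match("d", rooted$tip.label) %in% rooted$edge[kids, 2])
  expect_equal(sort(rooted$edge.length[kids]), rep(pend / 2, 2),
               tolerance = 1e-12)
  # round trip: unrooting recovers the original topology
  expect_identical(canonical_newick(ape::unroot(rooted)),
                   canonical_newick(tru))
  expect_error(root_with_taxon(tru, "zz"), "not found")
})

test_that("star trees are refused by rooted-tree-only operations", {
  star <- build_star_tree(letters[1:5])
  expect_error(is_basal_lineage(star, "a"), "not rooted")
  expect_error(root_with_taxon(star, "a"), "star")
})
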