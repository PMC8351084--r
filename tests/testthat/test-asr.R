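test_that("star tree construction and contracts", {
  star <- build_star_tree(letters[1:5])
  expect_true(is_star_tree(star))
  expect_equal(length(star$tip.label) + star$Nnode, 6L)  # 6 nodes
  expect_equal(nrow(star$edge), 5L)                      # 5 edges
  expect_error(build_star_tree(c("a", "b")), "at least 3")
  resolved <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_false(is_star_tree(resolved))
})

test_that("identical tip sequences reconstruct themselves", {
  star <- build_star_tree(c("a", "b", "c"), 0.3)
  aln <- alignment(c(a = "MKVL", b = "MKVL", c = "MKVL"), "aa")
  prof <- marginal_asr(star, aln, subst_model("LG"))
  expect_identical(prof$map_sequence, "MKVL")
  expect_lt(max(abs(rowSums(prof$posterior) - 1)), 1e-10)
})

test_that("three-tip one-site posterior equals the hand Bayes computation", {
  star <- build_star_tree(c("x", "y", "z"), 0.2)
  aln <- alignment(c(x = "A", y = "A", z = "C"), "nt")
  m <- subst_model("JC")
  prof <- marginal_asr(star, aln, m, optimize = FALSE)
  # oracle: posterior(s) prop. to pi_s P(s->A)^2 P(s->C) at t = 0.2
  P <- transition_probabilities(build_rate_matrix(m), 0.2)
  joint <- 0.25 * P[, "A"]^2 * P[, "C"]
  expect_equal(unname(prof$posterior[1, ]), unname(joint / sum(joint)),
               tolerance = 1e-10)
  expect_identical(prof$map_sequence, "A")
})

test_that("MAP ties are broken by alphabet order and flagged", {
  star <- build_star_tree(c("x", "y", "z", "w"), 0.2)
  # column: two As, two Cs -> symmetric posterior, tie between A and C
  aln <- alignment(c(x = "A", y = "A", z = "C", w = "C"), "nt")
  prof <- marginal_asr(star, aln, subst_model("JC"), optimize = FALSE)
  expect_identical(prof$map_sequence, "A")
  expect_equal(prof$ties, 1L)
})

test_that("posteriors are invariant to tip input order", {
  m <- subst_model("LG")
  star <- build_star_tree(paste0("t", 1:4), 0.1)
  aln <- random_alignment(4, 80, "aa", seed = 14)
  prof1 <- marginal_asr(star, aln, m, optimize = FALSE)
  perm <- structure(list(seq = aln$seq[c(3, 1, 4, 2), ], alphabet = "aa"),
                    class = "lca_alignment")
  prof2 <- marginal_asr(star, perm, m, optimize = FALSE)
  expect_equal(prof1$posterior, prof2$posterior, tolerance = 1e-12)
})

test_that("MAP posterior approaches 1 as branch lengths shrink with
           concordant tips", {
  aln <- alignment(c(a = "MK", b = "MK", c = "MK"), "aa")
  m <- subst_model("LG")
  post <- vapply(c(0.5, 0.05, 0.001), function(len) {
    star <- build_star_tree(c("a", "b", "c"), len)
    mean(marginal_asr(star, aln, m, optimize = FALSE)$map_posterior)
  }, 0)
  expect_true(all(diff(post) > 0))
  expect_gt(post[3], 0.999)
})

test_that("marginal_asr requires a star tree and matching taxa", {
  resolved <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- random_alignment(4, 20, "aa", seed = 2)
  expect_error(marginal_asr(resolved, aln, subst_model("LG")), "star")
  star <- build_star_tree(paste0("t", 1:5))
  expect_error(marginal_asr(star, aln, subst_model("LG")), "taxa differ|taxa")
})

test_that("star reconstruction recovers most of the true root sequence", {
  m <- subst_model("LG")
  star <- build_star_tree(paste0("t", 1:5), 0.05)
  aln <- simulate_alignment(simulation_spec(star, m, 1000, seed = 21))
  prof <- marginal_asr(star, aln, m)
  acc <- mean(strsplit(prof$map_sequence, "")[[1]] ==
                strsplit(attr(aln, "root_seq"), "")[[1]])
  expect_gte(acc, 0.95)
})

test_that("ancestral profile files are written", {
  star <- build_star_tree(c("a", "b", "c"), 0.1)
  aln <- alignment(c(a = "MKV", b = "MKV", c = "MRV"), "aa")
  prof <- marginal_asr(star, aln, subst_model("LG"))
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_ancestral_profile(prof, fasta = fa, tsv = tsv)
  expect_identical(sequence_strings(read_fasta_alignment(fa, "aa"))[["LCA"]],
                   prof$map_sequence)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 3)
})

test_that("lca_root refuses undersized ingroups and LCA name clashes", {
  aln <- random_alignment(4, 30, "aa", seed = 5)
  expect_error(lca_root(aln, "t4", subst_model("LG")), ">= 4 ingroup")
  aln2 <- random_alignment(5, 30, "aa", seed = 5)
  rownames(aln2$seq)[5] <- "LCA"
  expect_error(lca_root(aln2, NA, subst_model("LG")), "LCA")
})

test_that("identical strain tips remain a cherry in the LCA-rooted tree and
           the LCA pendant branch is reported", {
  sc <- make_lba_scenario(lba_scenario_spec(strain_divergence = 0,
                                            n_sites = 600, seed = 4))
  lr <- lca_root(sc$alignment, "outgroup", subst_model("POISSON"))
  expect_true(has_clade(lr$rooted_ingroup, c("seison_A", "seison_B")))
  expect_gte(lr$lca_branch_length, 0)
  expect_equal(sort(lr$rooted_ingroup$tip.label),
               sort(taxa(sc$ingroup_alignment)))
})

test_that("on no-LBA data the LCA pendant branch is near zero and LCA and
           outgroup rooting agree", {
  truth <- ape::read.tree(text = paste0(
    "(((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1):0.05,out:0.4);"))
  m <- subst_model("LG")
  lens <- c(); agree <- c()
  for (s in 1:5) {
    aln <- simulate_alignment(simulation_spec(truth, m, 2000, seed = s))
    lr <- lca_root(aln, "out", m)
    lens <- c(lens, lr$lca_branch_length)
    srch <- ml_tree_search(aln, m)
    rooted <- root_with_taxon(srch$best_tree, "out")
    ing <- ape::drop.tip(rooted, "out")
    agree <- c(agree, canonical_newick(ing, rooted = TRUE) ==
                 canonical_newick(lr$rooted_ingroup, rooted = TRUE))
  }
  expect_lt(median(lens), 0.05)
  expect_gte(sum(agree), 4)
})
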