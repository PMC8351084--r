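test_that("two identical one-site sequences match the JC pair closed form", {
  for (t in c(0.1, 0.5, 2)) {
    aln <- alignment(c(a = "A", b = "A"), "nt")
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t / 2, t / 2))
    got <- log_likelihood(tr, aln, subst_model("JC"))$logLik
    expect_equal(got, log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))),
                 tolerance = 1e-12)
  }
})

test_that("pruning equals brute-force enumeration (JC+G4, gaps included)", {
  tr <- random_bl_tree("((a,b),(c,d));", seed = 1, lo = 0.05, hi = 1.5)
  aln <- alignment(c(a = "ACGTAC-T", b = "ACGTTTGT",
                     c = "AAGTACGN", d = "CCGTACGT"), "nt")
  m <- subst_model("JC+G4+I", alpha = 0.8, p_inv = 0.15)
  expect_equal(log_likelihood(tr, aln, m)$logLik,
               brute_force_loglik(tr, aln, m), tolerance = 1e-10)
})

test_that("all-zero branch lengths with a variable column give -Inf", {
  aln <- alignment(c(a = "AA", b = "AC"), "nt")
  tr <- ape::read.tree(text = "(a:0,b:0);")
  expect_warning(fit <- log_likelihood(tr, aln, subst_model("JC")), "-Inf")
  expect_identical(fit$logLik, -Inf)
})

test_that("total equals the sum of per-site log-likelihoods; constant-column
           additivity holds", {
  tr <- random_bl_tree("((a,b),(c,d),e);", seed = 3, lo = 0.05, hi = 0.5)
  aln <- random_alignment(5, 60, "nt", seed = 6)
  rownames(aln$seq) <- c("a", "b", "c", "d", "e")
  m <- subst_model("JC+G4", alpha = 1)
  fit <- log_likelihood(tr, aln, m)
  expect_equal(fit$logLik, sum(fit$site_loglik), tolerance = 1e-8)
  plus <- alignment(cbind(aln$seq, matrix("A", 5, 1,
                                          dimnames = list(taxa(aln), NULL))),
                    "nt")
  fit2 <- log_likelihood(tr, plus, m)
  expect_equal(fit2$logLik - fit$logLik, fit2$site_loglik[61],
               tolerance = 1e-8)
})

test_that("pulley principle: lnL is invariant to the virtual root", {
  tr <- random_bl_tree("((a,b),(c,d),e);", seed = 4, lo = 0.05, hi = 0.8)
  aln <- simulate_alignment(
    simulation_spec(tr, subst_model("JC+G4", alpha = 0.6), 150, seed = 2))
  m <- subst_model("JC+G4+I", alpha = 0.6, p_inv = 0.1)
  ref <- log_likelihood(tr, aln, m)$logLik
  for (tip in tr$tip.label[1:3]) {
    rooted <- root_with_taxon(tr, tip)
    expect_equal(log_likelihood(rooted, aln, m)$logLik, ref,
                 tolerance = 1e-8)
  }
})

test_that("engine agrees with phangorn across model families", {
  tr <- random_bl_tree("((a,b),(c,d),e);", seed = 5, lo = 0.05, hi = 0.8)
  m <- subst_model("LG+G4", alpha = 0.7)
  aln <- simulate_alignment(simulation_spec(tr, m, 300, seed = 9))
  pd <- as_phyDat(aln)
  expect_equal(log_likelihood(tr, aln, m)$logLik,
               phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.7)$logLik,
               tolerance = 1e-8)
  m2 <- subst_model("LG+G4+I+F", alpha = 0.7, p_inv = 0.2)
  expect_equal(
    log_likelihood(tr, aln, m2)$logLik,
    phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.7, inv = 0.2,
                  bf = empirical_frequencies(aln))$logLik,
    tolerance = 1e-8)
  trn <- random_bl_tree("((a,b),(c,d));", seed = 6, lo = 0.05, hi = 0.5)
  mn <- subst_model("GTR+G4", alpha = 0.5,
                    gtr_rates = c(1.5, 4, 0.7, 1.2, 5, 1),
                    frequencies = c(0.4, 0.3, 0.2, 0.1))
  alnn <- simulate_alignment(simulation_spec(trn, mn, 400, seed = 2))
  expect_equal(
    log_likelihood(trn, alnn, mn)$logLik,
    phangorn::pml(trn, as_phyDat(alnn), model = "GTR", k = 4, shape = 0.5,
                  bf = c(0.4, 0.3, 0.2, 0.1),
                  Q = c(1.5, 4, 0.7, 1.2, 5, 1))$logLik,
    tolerance = 1e-8)
})

test_that("branch-length optimization recovers the JC distance MLE", {
  sim <- simulate_alignment(simulation_spec(
    ape::read.tree(text = "(a:0.08,b:0.08);"), subst_model("JC"), 3000,
    seed = 3))
  p <- mean(sim$seq[1, ] != sim$seq[2, ])
  res <- optimize_branch_lengths(ape::read.tree(text = "(a:0.3,b:0.3);"),
                                 sim, subst_model("JC"))
  expect_equal(sum(res$tree$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-4)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  aln <- alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"), "nt")
  tr <- ape::read.tree(text = "(a:0.2,b:0.2,c:0.2);")
  res <- optimize_branch_lengths(tr, aln, subst_model("JC"))
  expect_true(all(res$tree$edge.length <= 1e-6))
  expect_true(res$fit$converged)
})

test_that("branch lengths are recovered within tolerance on simulated data", {
  truth <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1,e:0.1);")
  m <- subst_model("LG")
  hits <- vapply(1:20, function(s) {
    aln <- simulate_alignment(simulation_spec(truth, m, 5000, seed = s))
    start <- truth
    start$edge.length <- rep(0.3, nrow(truth$edge))
    res <- optimize_branch_lengths(start, aln, m)
    key <- function(tr) {
      ord <- order(tr$edge[, 1], tr$edge[, 2])
      tr$edge.length[ord]
    }
    all(abs(key(res$tree) - key(ape::reorder.phylo(truth, "postorder")))
        <= 0.02)
  }, TRUE)
  expect_gte(sum(hits), 18)   # >= 90% of 20 seeds
})

test_that("gamma shape and p_inv are recovered; fixed-parameter fit matches
           plain branch optimization", {
  truth <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1,(e:0.1,f:0.1):0.1);")
  gen <- subst_model("LG+G4", alpha = 0.5)
  ok_alpha <- vapply(1:20, function(s) {
    aln <- simulate_alignment(simulation_spec(truth, gen, 5000, seed = s))
    ft <- fit_model_parameters(truth, aln, subst_model("LG+G4"))
    ft$fit$alpha >= 0.35 && ft$fit$alpha <= 0.70
  }, TRUE)
  expect_gte(sum(ok_alpha), 16)   # >= 80% of 20 seeds
  gen0 <- subst_model("LG")       # no invariant sites in truth
  ok_pinv <- vapply(1:10, function(s) {
    aln <- simulate_alignment(simulation_spec(truth, gen0, 2000, seed = s))
    ft <- fit_model_parameters(truth, aln, subst_model("LG+I"))
    ft$fit$p_inv < 0.05
  }, TRUE)
  expect_gte(sum(ok_pinv), 8)
  # no free parameters: fit reduces to branch-length optimization
  aln <- simulate_alignment(simulation_spec(truth, gen, 1000, seed = 77))
  fixed <- subst_model("LG+G4", alpha = 0.5)
  a <- fit_model_parameters(truth, aln, fixed)
  b <- optimize_branch_lengths(truth, aln, fixed)
  expect_equal(a$fit$logLik, b$fit$logLik, tolerance = 1e-3)
})

test_that("AIC ranks by penalized likelihood with ties to fewer parameters", {
  truth <- random_bl_tree("((a,b),(c,d));", seed = 10, lo = 0.1, hi = 0.3)
  gen <- subst_model("GTR+G4", alpha = 0.5,
                     gtr_rates = c(2, 8, 1, 1.5, 9, 1),
                     frequencies = c(0.45, 0.3, 0.15, 0.1))
  aln <- simulate_alignment(simulation_spec(truth, gen, 1500, seed = 4))
  tab <- aic_select(aln, truth, list("JC", "GTR+G4"))
  expect_equal(tab$model[1], "GTR+G4")
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  expect_error(aic_select(aln, truth, list("JC")), "at least 2")
})

test_that("per-site lnL dump round-trips", {
  tr <- random_bl_tree("((a,b),(c,d));", seed = 2, lo = 0.1, hi = 0.3)
  aln <- simulate_alignment(simulation_spec(tr, subst_model("JC"), 50, seed = 1))
  fit <- log_likelihood(tr, aln, subst_model("JC"))
  f <- tempfile(fileext = ".tsv")
  write_site_loglik(fit, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 50)
  expect_equal(sum(tab$loglik), fit$logLik, tolerance = 1e-8)
})
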