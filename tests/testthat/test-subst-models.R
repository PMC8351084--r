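test_that("model grammar parses and validates", {
  m <- subst_model("LG+G4+I+F")
  expect_equal(m$base, "LG")
  expect_true(m$has_gamma && m$has_inv)
  expect_equal(m$k, 4L)
  expect_equal(m$freqs_mode, "empirical")
  expect_equal(subst_model("GTR+G8")$k, 8L)
  expect_equal(subst_model("LG+G")$k, 4L)     # default category count
  expect_error(subst_model("WAG"), "unknown base model")
  expect_error(subst_model("LG+Q"), "unknown model flag")
  expect_error(subst_model("JC+F"), "fixed equal frequencies")
  expect_error(subst_model("LG", alpha = -1), "alpha")
  expect_error(subst_model("LG+I", p_inv = 1), "p_inv")
})

test_that("JC rate matrix has the closed form", {
  rm <- build_rate_matrix(subst_model("JC"))
  expect_equal(unname(diag(rm$Q)), rep(-1, 4))
  off <- rm$Q[row(rm$Q) != col(rm$Q)]
  expect_equal(unname(off), rep(1 / 3, 12))
})

test_that("rate matrices are stationary, reversible and unit-rate", {
  freqs <- c(0.5, 0.2, 0.2, 0.1)
  for (m in list(subst_model("LG"),
                 subst_model("GTR", gtr_rates = c(2, 6, 1, 1.3, 8, 1),
                             frequencies = freqs))) {
    rm <- build_rate_matrix(m)
    pi <- rm$pi
    expect_lt(max(abs(pi %*% rm$Q)), 1e-10)                    # stationarity
    DB <- diag(pi) %*% rm$Q
    expect_lt(max(abs(DB - t(DB))), 1e-12)                     # reversibility
    expect_equal(-sum(pi * diag(rm$Q)), 1, tolerance = 1e-12)  # unit rate
    expect_lt(max(abs(rowSums(rm$Q))), 1e-12)
  }
  expect_error(build_rate_matrix(subst_model("LG"),
                                 freqs = c(rep(1 / 19, 19), 0)),
               "zero")
})

test_that("LG+F differs from LG only through the frequency weighting", {
  m1 <- subst_model("LG")
  rm1 <- build_rate_matrix(m1)
  skew <- exp(seq(-1, 1, length.out = 20)); skew <- skew / sum(skew)
  rm2 <- build_rate_matrix(m1, freqs = skew)
  # same exchangeabilities: Q_ij / pi_j identical up to global rescale
  S1 <- rm1$Q / rep(rm1$pi, each = 20)
  S2 <- rm2$Q / rep(rm2$pi, each = 20)
  diag(S1) <- diag(S2) <- 0
  ratio <- S2[S1 > 0] / S1[S1 > 0]
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("transition probabilities: identity, JC closed form, ergodic limit", {
  rmj <- build_rate_matrix(subst_model("JC"))
  expect_equal(transition_probabilities(rmj, 0), diag(4),
               ignore_attr = TRUE, tolerance = 1e-12)
  for (t in c(0.01, 0.3, 2)) {
    P <- transition_probabilities(rmj, t)
    dexp <- 0.25 + 0.75 * exp(-4 * t / 3)
    oexp <- 0.25 - 0.25 * exp(-4 * t / 3)
    expect_equal(unname(diag(P)), rep(dexp, 4), tolerance = 1e-12)
    expect_equal(unname(P[row(P) != col(P)]), rep(oexp, 12), tolerance = 1e-12)
  }
  rml <- build_rate_matrix(subst_model("LG"))
  P500 <- transition_probabilities(rml, 500)
  expect_lt(max(abs(sweep(P500, 2, rml$pi, "-"))), 1e-8)
  expect_lt(max(abs(rowSums(P500) - 1)), 1e-12)
  expect_error(transition_probabilities(rml, -1), ">= 0")
})

test_that("Chapman-Kolmogorov and pointwise reversibility hold", {
  rml <- build_rate_matrix(subst_model("LG"))
  set.seed(42)
  for (i in 1:5) {
    s <- runif(1, 0, 2); t <- runif(1, 0, 2)
    expect_lt(max(abs(transition_probabilities(rml, s) %*%
                        transition_probabilities(rml, t) -
                        transition_probabilities(rml, s + t))), 1e-10)
    P <- transition_probabilities(rml, t)
    F1 <- diag(rml$pi) %*% P
    expect_lt(max(abs(F1 - t(F1))), 1e-10)
  }
})

test_that("discrete gamma categories have mean one and match quadrature", {
  expect_equal(discrete_gamma_rates(2, 1)$rates, 1)
  rc <- discrete_gamma_rates(1, 4)
  expect_equal(sum(rc$rates * rc$weights), 1, tolerance = 1e-12)
  # independent quadrature oracle: mean of Gamma(a, a) over quantile bins
  a <- 0.5; k <- 4
  b <- qgamma(seq(0, 1, length.out = k + 1), a, a)
  oracle <- vapply(seq_len(k), function(i) {
    integrate(function(x) x * dgamma(x, a, a), b[i], b[i + 1],
              rel.tol = 1e-10)$value * k
  }, 0)
  expect_equal(discrete_gamma_rates(a, k)$rates, oracle, tolerance = 1e-6)
  # invariant category bookkeeping
  rci <- discrete_gamma_rates(1, 4, p_inv = 0.3)
  expect_equal(rci$rates[1], 0)
  expect_equal(rci$weights[1], 0.3)
  expect_equal(sum(rci$rates * rci$weights), 1, tolerance = 1e-12)
  expect_error(discrete_gamma_rates(0, 4), "alpha")
  expect_error(discrete_gamma_rates(1, 0), "k must be")
})

test_that("gamma discretization refines towards the continuous mixture", {
  tr <- random_bl_tree("((a,b),(c,d));", seed = 2, lo = 0.1, hi = 0.6)
  aln <- simulate_alignment(
    simulation_spec(tr, subst_model("JC"), 300, seed = 8))
  ref <- log_likelihood(tr, aln, subst_model("JC+G64", alpha = 0.5))$logLik
  lls <- vapply(c(4, 8, 16), function(k) {
    log_likelihood(tr, aln,
                   subst_model(sprintf("JC+G%d", k), alpha = 0.5))$logLik
  }, 0)
  gaps <- abs(lls - ref)
  expect_true(all(diff(gaps) < 0))
})

test_that("empirical frequencies count non-gap residues and floor zeros", {
  aln <- alignment(c(a = "AAAA", b = "AAAA"), "nt")
  f <- empirical_frequencies(aln)
  expect_equal(unname(f["A"]), 1 / (1 + 3e-6), tolerance = 1e-9)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_true(all(f[c("C", "G", "T")] > 0))
  gapped <- alignment(c(a = "A-", b = "A-"), "nt")
  f2 <- empirical_frequencies(gapped)
  expect_equal(unname(f2["A"]), unname(f["A"]))  # gaps excluded from the count
  allgap <- alignment(c(a = "--", b = "--"), "nt")
  expect_error(empirical_frequencies(allgap), "only gap")
  big <- random_alignment(10, 10000, "aa", seed = 4)
  expect_lt(max(abs(empirical_frequencies(big) - 0.05)), 0.01)
})

test_that("PAML dat parsing rebuilds a symmetric matrix and frequencies", {
  f <- tempfile(fileext = ".dat")
  set.seed(9)
  vals <- round(runif(190, 0.01, 5), 4)
  freqs <- round(runif(20, 1, 10), 3)
  writeLines(c(paste(vals, collapse = " "), paste(freqs, collapse = " ")), f)
  parsed <- parse_paml_dat(f)
  expect_equal(parsed$S, t(parsed$S))
  expect_equal(sum(parsed$freqs), 1, tolerance = 1e-12)
  expect_equal(parsed$S[2, 1], vals[1])
  expect_equal(parsed$S[20, 19], vals[190])
  m <- subst_model("LG", exchangeabilities = parsed)
  expect_equal(m$S[3, 1], vals[2])
})
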