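# Independent oracles used across the suite. These deliberately avoid the
# package's pruning engine: likelihoods are computed by brute-force
# enumeration over internal-node states, singletons by per-column counting
# with table().

# brute-force log-likelihood: per site and rate category, sum the joint
# probability over all assignments of states to internal nodes
brute_force_loglik <- function(tree, aln, model) {
  cm <- lcaroot:::resolve_model(model, aln)
  tre <- ape::reorder.phylo(tree, "postorder")
  codes <- lcaroot:::alignment_codes(aln)[tre$tip.label, , drop = FALSE]
  ns <- length(cm$pi)
  ntip <- length(tre$tip.label)
  nint <- tre$Nnode
  root <- ntip + 1L
  combos <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  Ps <- lapply(seq_along(cm$rates), function(k)
    lapply(seq_len(nrow(tre$edge)), function(e)
      transition_probabilities(cm$rm, tre$edge.length[e], cm$rates[k])))
  site_ll <- vapply(seq_len(ncol(codes)), function(j) {
    tot <- 0
    for (k in seq_along(cm$rates)) {
      lik <- 0
      for (r in seq_len(nrow(combos))) {
        assign_state <- function(v) {
          if (v <= ntip) codes[v, j] else combos[r, v - ntip]
        }
        p <- cm$pi[combos[r, root - ntip]]
        for (e in seq_len(nrow(tre$edge))) {
          sp <- assign_state(tre$edge[e, 1])
          sc <- assign_state(tre$edge[e, 2])
          p <- p * if (sc == 0) 1 else Ps[[k]][[e]][sp, sc]
        }
        lik <- lik + p
      }
      tot <- tot + cm$weights[k] * lik
    }
    if (cm$p_inv > 0) {
      nz <- unique(codes[, j][codes[, j] > 0])
      if (length(nz) == 1) tot <- tot + cm$p_inv * cm$pi[nz]
      if (length(nz) == 0) tot <- tot + cm$p_inv
    }
    log(tot)
  }, 0)
  sum(site_ll)
}

# per-column counting oracle for singleton positions
brute_force_singletons <- function(aln) {
  miss <- lcaroot:::missing_chars(aln$alphabet)
  which(vapply(seq_len(n_sites(aln)), function(j) {
    col <- aln$seq[, j]
    tab <- table(col[!(col %in% miss)])
    any(tab == 1)
  }, TRUE))
}

random_alignment <- function(ntaxa, L, alphabet = "nt", seed = 1,
                             gap_prob = 0) {
  states <- lcaroot:::alphabet_states(alphabet)
  lcaroot:::with_seed(seed, {
    m <- matrix(sample(states, ntaxa * L, replace = TRUE), ntaxa, L)
    if (gap_prob > 0)
      m[runif(length(m)) < gap_prob] <- "-"
    rownames(m) <- paste0("t", seq_len(ntaxa))
    alignment(m, alphabet)
  })
}

random_bl_tree <- function(newick, seed, lo = 0.05, hi = 1) {
  tr <- ape::read.tree(text = newick)
  lcaroot:::with_seed(seed, {
    tr$edge.length <- runif(nrow(tr$edge), lo, hi)
    tr
  })
}
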