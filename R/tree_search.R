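# Exhaustive ML topology search for small taxon sets (<= 8 taxa, at most
# 10395 unrooted topologies), with NNLS-seeded branch lengths, optional
# likelihood prescreening, and nonparametric bootstrap support.

#' Enumerate all unrooted binary topologies
#'
#' Complete, duplicate-free enumeration by stepwise leaf insertion
#' (delegated to [phangorn::allTrees()]), returned sorted by canonical
#' Newick so downstream processing is deterministic. Hard-capped at 8 taxa
#' (10395 topologies): the search is exhaustive by design and is meant for
#' the handful of OTUs that deep-split rooting questions involve.
#'
#' @param taxa_labels 3 to 8 unique labels.
#' @return A `multiPhylo` of `(2n-5)!!` topologies (no branch lengths).
#' @export
enumerate_unrooted_topologies <- function(taxa_labels) {
  n <- length(taxa_labels)
  if (n < 3 || n > 8)
    stop("exhaustive enumeration supports 3..8 taxa (got ", n, "); the ",
         "search is exhaustive by design, not a heuristic for large trees")
  if (anyDuplicated(taxa_labels)) stop("duplicate taxon labels")
  trees <- phangorn::allTrees(n, rooted = FALSE,
                              tip.label = sort(as.character(taxa_labels)))
  # materialize per-tree tip labels (multiPhylo objects may hoist them)
  trees <- ape::.uncompressTipLabel(trees)
  expected <- double_factorial_topologies(n)
  keys <- vapply(trees, canonical_newick, "")
  if (anyDuplicated(keys) || length(trees) != expected)
    stop("internal error: enumeration produced ", length(trees),
         " topologies (", length(unique(keys)), " unique), expected ",
         expected)
  trees[order(keys)]
}

# Pairwise ML distances under the (concrete) model; used to seed branch
# lengths via NNLS before likelihood screening.
ml_distance_matrix <- function(aln, cm) {
  labs <- taxa(aln)
  codes <- alignment_codes(aln)
  n <- length(labs)
  ns <- length(cm$pi)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- codes[i, ] > 0 & codes[j, ] > 0
    if (!any(ok)) { D[i, j] <- D[j, i] <- 0.5; next }
    counts <- table(factor(codes[i, ok], levels = 1:ns),
                    factor(codes[j, ok], levels = 1:ns))
    counts <- unclass(counts)
    same <- sum(diag(counts))
    if (same == sum(counts)) { D[i, j] <- D[j, i] <- 1e-6; next }
    nll <- function(t) {
      M <- matrix(0, ns, ns)
      for (k in seq_along(cm$rates))
        M <- M + cm$weights[k] * transition_probabilities(cm$rm, t, cm$rates[k])
      if (cm$p_inv > 0) diag(M) <- diag(M) + cm$p_inv
      M <- M * cm$pi
      -sum(counts * log(pmax(M, 1e-300)))
    }
    op <- optimize(nll, c(1e-6, 50))
    D[i, j] <- D[j, i] <- op$minimum
  }
  D
}

# NNLS branch lengths for a topology given a distance matrix
nnls_lengths <- function(topology, D) {
  fit <- phangorn::nnls.phylo(topology, D)
  fit$edge.length <- pmax(fit$edge.length, 1e-8)
  fit
}

#' Exhaustive maximum-likelihood topology search
#'
#' Enumerates every unrooted topology over the alignment's taxa, seeds each
#' with NNLS branch lengths fitted to pairwise ML distances, and optimizes.
#' Free model parameters (if any) are estimated once on the best
#' prescreened topology and then held fixed across the search; they are
#' shared by all topologies.
#'
#' For taxon sets with many topologies a likelihood prescreen at the NNLS
#' branch lengths ranks all candidates first, and only the top `screen_k`
#' receive full branch-length optimization (the rest keep their screening
#' score, flagged `optimized = FALSE` in the table). Set `screen_k = Inf` to
#' optimize every topology.
#'
#' @param aln An [alignment()].
#' @param model A [subst_model()]; free (NA) parameters are estimated.
#' @param screen_k Number of prescreened topologies to optimize fully
#'   (default 10; all topologies when the set has at most `screen_k + 5`
#'   members).
#' @param ... Branch-length optimization control, see
#'   [optimize_branch_lengths()].
#' @return A list of class `"lca_search"`: `table` (canonical Newick, lnL,
#'   delta lnL, optimized flag, ranked by lnL with lexicographic canonical
#'   Newick as tie-break), `best_tree` (optimized `phylo`), `best_fit`
#'   (`"lca_fit"`), `cm` (fitted model internals).
#' @export
ml_tree_search <- function(aln, model, screen_k = 10, ...) {
  if (n_taxa(aln) > 8)
    stop("exhaustive search supports at most 8 taxa; got ", n_taxa(aln))
  topos <- enumerate_unrooted_topologies(taxa(aln))
  # per-topology optimization can be a little looser than a final fit:
  # topology ranking is driven by lnL differences orders of magnitude larger
  ctrl <- utils::modifyList(default_optim_control(tol = 1e-4, max_passes = 12),
                            list(...))
  ctrl <- ctrl[c("min_len", "max_len", "tol", "max_passes", "brent_tol",
                 "brent_maxit")]

  # provisional concrete model for distances/screening (free params at
  # starting values)
  model0 <- model
  if (model0$has_gamma && is.na(model0$alpha)) model0$alpha <- 1
  if (model0$has_inv && is.na(model0$p_inv)) model0$p_inv <- 0.1
  if (model0$base == "GTR" && anyNA(model0$gtr_rates))
    model0$gtr_rates <- rep(1, 6)
  cm <- resolve_model(model0, aln)

  D <- ml_distance_matrix(aln, cm)
  seeded <- lapply(topos, nnls_lengths, D = D)
  cp0 <- compress_patterns(aln, taxa(aln))
  screen_lnl <- vapply(seeded, function(tr) {
    ed <- engine_data(tr, aln, cm, cp = cp0)
    do.call(eng_loglik, ed$args)$loglik
  }, 0)

  # estimate free model parameters once, on the screening winner
  needs_fit <- (model$has_gamma && is.na(model$alpha)) ||
    (model$has_inv && is.na(model$p_inv)) ||
    (model$base == "GTR" && anyNA(model$gtr_rates))
  if (needs_fit) {
    best0 <- seeded[[which.max(screen_lnl)]]
    ft0 <- fit_model_parameters(best0, aln, model, ...)
    cm <- ft0$cm
    model0 <- cm$model
    screen_lnl <- vapply(seeded, function(tr) {
      ed <- engine_data(tr, aln, cm, cp = cp0)
      do.call(eng_loglik, ed$args)$loglik
    }, 0)
  }

  keys <- vapply(topos, canonical_newick, "")
  k_opt <- if (length(topos) <= screen_k + 5) length(topos)
           else min(screen_k, length(topos))
  # deterministic selection: screening lnL desc, canonical Newick asc
  ord <- order(-screen_lnl, keys)
  opt_idx <- ord[seq_len(k_opt)]

  lnl <- screen_lnl
  optimized <- rep(FALSE, length(topos))
  opt_trees <- vector("list", length(topos))
  for (i in opt_idx) {
    ed <- engine_data(seeded[[i]], aln, cm, cp = cp0)
    res <- do.call(eng_optim_bl, c(ed$args, ctrl))
    tre <- ed$tree
    tre$edge.length <- res$lens
    opt_trees[[i]] <- tre
    lnl[i] <- res$loglik
    optimized[i] <- TRUE
  }
  ord2 <- order(-lnl, keys)
  tab <- data.frame(topology = keys[ord2], logLik = lnl[ord2],
                    delta_logLik = lnl[ord2][1] - lnl[ord2],
                    optimized = optimized[ord2], stringsAsFactors = FALSE)
  best_i <- ord2[1]
  best_tree <- opt_trees[[best_i]]
  ed <- engine_data(best_tree, aln, cm)
  res <- do.call(eng_loglik, ed$args)
  best_fit <- make_fit(ed$tree, aln, cm$model, cm, res$loglik, res$site,
                       ed$cp$site_of)
  structure(list(table = tab, best_tree = best_tree, best_fit = best_fit,
                 cm = cm, n_topologies = length(topos)),
            class = "lca_search")
}

#' @export
print.lca_search <- function(x, ...) {
  cat(sprintf("<exhaustive ML search> %d topologies, best lnL = %.4f\n",
              x$n_topologies, x$table$logLik[1]))
  print(head(x$table, 5))
  invisible(x)
}

#' Nonparametric bootstrap support for a topology
#'
#' Draws `B` site-resampled replicates (columns with replacement, original
#' length), runs the full exhaustive search on each, and reports for every
#' internal bipartition of `topology` the fraction of replicate best trees
#' that contain it. Seed-reproducible; supports are invariant to taxon input
#' order.
#'
#' @param aln An [alignment()].
#' @param model A [subst_model()].
#' @param topology The tree whose internal edges are scored (typically the
#'   ML tree).
#' @param B Number of replicates, >= 1.
#' @param seed Integer seed.
#' @param ... Passed to [ml_tree_search()].
#' @return A list of class `"lca_support"`: `tree` (topology with node
#'   labels set to supports), `support` (named numeric vector keyed by
#'   bipartition), `B`.
#' @export
bootstrap_support <- function(aln, model, topology, B, seed = 1, ...) {
  if (!is.numeric(B) || B < 1) stop("B must be >= 1")
  B <- as.integer(B)
  splits <- bipartitions(topology)
  hits <- setNames(numeric(length(splits)), splits)
  L <- n_sites(aln)
  reps <- with_seed(seed, lapply(seq_len(B), function(b)
    sample.int(L, L, replace = TRUE)))
  for (b in seq_len(B)) {
    ralg <- structure(list(seq = aln$seq[, reps[[b]], drop = FALSE],
                           alphabet = aln$alphabet), class = "lca_alignment")
    rs <- ml_tree_search(ralg, model, ...)
    found <- bipartitions(rs$best_tree)
    hits[splits %in% found] <- hits[splits %in% found] + 1
  }
  support <- hits / B
  tree <- annotate_support(topology, support)
  structure(list(tree = tree, support = support, B = B),
            class = "lca_support")
}

# write bipartition supports into a phylo's node labels
annotate_support <- function(tree, support) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  all_taxa <- sort(tree$tip.label)
  ref <- all_taxa[1]
  labs <- rep("", tree$Nnode)
  ch <- node_children(tree)
  fill <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    tips <- sort(unlist(lapply(ch[[v]], fill)))
    if (length(tips) > 1 && length(tips) < ntip - 1) {
      side <- if (ref %in% tips) setdiff(all_taxa, tips) else tips
      key <- paste(sort(side), collapse = "|")
      if (key %in% names(support))
        labs[v - ntip] <<- format(support[[key]], digits = 3)
    }
    tips
  }
  fill(ntip + 1L)
  tree$node.label <- labs
  tree
}
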