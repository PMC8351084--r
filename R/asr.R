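# Marginal ancestral sequence reconstruction at the central node of a
# star-topology tree, and rooting via the reconstructed last-common-ancestor
# (LCA) sequence used as a surrogate outgroup.

#' Marginal ancestral reconstruction on a star tree
#'
#' Branch lengths (and any free model parameters) are first ML-optimized on
#' the star tree; then, per site and rate category, the posterior
#' distribution of the central-node state is computed as
#' \eqn{\propto \pi_s \prod_{tips} P(s \to x_{tip}; t_{tip} r)} and mixed
#' over categories by their weights (the invariant category contributes at
#' constant-capable sites). Because the star encodes no relationships, the
#' reconstruction is unbiased with respect to the ingroup phylogeny.
#'
#' @param star A star tree from [build_star_tree()] whose tips match the
#'   alignment's taxa.
#' @param aln An [alignment()].
#' @param model A [subst_model()]; free parameters are estimated on the
#'   star tree.
#' @param optimize Optimize star branch lengths / parameters first (default
#'   `TRUE`)?
#' @param ... Optimization control, see [optimize_branch_lengths()].
#' @return An object of class `"ancestral_profile"`: `posterior` (L x
#'   n_states matrix, rows sum to 1), `map_sequence` (string), `map_posterior`
#'   (per-site posterior of the MAP state), `ties` (1-based sites whose MAP
#'   state was tie-broken by alphabet order), `tree` (the fitted star),
#'   `fit`.
#' @export
marginal_asr <- function(star, aln, model, optimize = TRUE, ...) {
  if (!is_star_tree(star))
    stop("marginal_asr() reconstructs at the central node of a star tree; ",
         "use build_star_tree()")
  if (!setequal(star$tip.label, taxa(aln)))
    stop("star tree tips and alignment taxa differ")
  fitted <- fit_model_parameters(star, aln, model,
                                 optimize_edges = optimize, ...)
  cm <- fitted$cm
  tree <- fitted$tree
  st <- alphabet_states(aln$alphabet)
  ns <- length(st)
  cp <- compress_patterns(aln, tree$tip.label)
  npat <- ncol(cp$pat)
  nc <- length(cm$rates)
  tiplens <- tree$edge.length[match(seq_along(tree$tip.label),
                                    tree$edge[, 2])]

  post <- matrix(0, ns, npat)
  for (k in seq_len(nc)) {
    logj <- matrix(log(cm$pi), ns, npat)
    for (i in seq_along(tree$tip.label)) {
      P <- transition_probabilities(cm$rm, tiplens[i], cm$rates[k])
      lP <- log(pmax(P, 1e-300))
      xs <- cp$pat[i, ]
      contrib <- matrix(0, ns, npat)
      obs <- xs > 0
      contrib[, obs] <- lP[, xs[obs]]
      logj <- logj + contrib
    }
    post <- post + cm$weights[k] * exp(logj)
  }
  if (cm$p_inv > 0) {
    for (j in seq_len(npat)) {
      if (cp$cs[j] > 0)
        post[cp$cs[j], j] <- post[cp$cs[j], j] + cm$p_inv * cm$pi[cp$cs[j]]
      else if (cp$cs[j] == -1)
        post[, j] <- post[, j] + cm$p_inv * cm$pi
    }
  }
  norm <- colSums(post)
  if (any(norm <= 0)) stop("zero posterior mass at some site; degenerate model")
  post <- sweep(post, 2, norm, "/")
  map_idx <- apply(post, 2, which.max)  # which.max takes first = alphabet order
  tie_pat <- vapply(seq_len(npat), function(j)
    sum(abs(post[, j] - post[map_idx[j], j]) < 1e-12) > 1, TRUE)
  post_sites <- t(post[, cp$site_of, drop = FALSE])
  colnames(post_sites) <- st
  map_sites <- map_idx[cp$site_of]
  structure(list(
    posterior = post_sites,
    map_sequence = paste(st[map_sites], collapse = ""),
    map_posterior = post[cbind(map_idx, seq_len(npat))][cp$site_of],
    ties = which(tie_pat[cp$site_of]),
    tree = tree, fit = fitted$fit
  ), class = "ancestral_profile")
}

#' @export
print.ancestral_profile <- function(x, ...) {
  L <- nrow(x$posterior)
  cat(sprintf("<ancestral profile> %d sites, mean MAP posterior %.3f", L,
              mean(x$map_posterior)))
  if (length(x$ties) > 0)
    cat(sprintf(", %d tie-broken site(s)", length(x$ties)))
  cat("\n")
  invisible(x)
}

#' Write an ancestral profile to disk
#'
#' The MAP (LCA) sequence as FASTA plus the full per-site posterior matrix
#' as TSV.
#'
#' @param profile An `"ancestral_profile"`.
#' @param fasta,tsv Output paths (either may be `NULL` to skip).
#' @param name Sequence name in the FASTA.
#' @return Invisibly, `profile`.
#' @export
write_ancestral_profile <- function(profile, fasta = NULL, tsv = NULL,
                                    name = "LCA") {
  if (!is.null(fasta)) {
    aln <- alignment(setNames(profile$map_sequence, name),
                     alphabet = if (ncol(profile$posterior) == 20) "aa" else "nt")
    write_fasta_alignment(aln, fasta)
  }
  if (!is.null(tsv)) {
    df <- data.frame(site = seq_len(nrow(profile$posterior)),
                     map_posterior = profile$map_posterior,
                     profile$posterior, check.names = FALSE)
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(profile)
}

#' Root an ingroup tree with a reconstructed ancestral sequence
#'
#' The LCA-rooting pipeline: drop the outgroup, reconstruct the ingroup's
#' last-common-ancestor sequence by [marginal_asr()] on a star tree, add the
#' MAP sequence to the ingroup alignment as a surrogate outgroup tip
#' (`"LCA"`), run the exhaustive ML search (optionally with bootstrap), and
#' root the best tree on the LCA tip's pendant edge. Unlike rooting with a
#' distant outgroup, the surrogate sits close to the ingroup's root, so it
#' cannot attract fast-evolving ingroup branches.
#'
#' @param aln Alignment containing the ingroup taxa and (optionally) the
#'   outgroup. The full-length (unpruned) alignment should be used.
#' @param outgroup_label Outgroup taxon to discard (may be `NA` if `aln`
#'   contains only the ingroup).
#' @param model A [subst_model()].
#' @param B Bootstrap replicates for support values (0 = skip).
#' @param seed Seed for the bootstrap resampling.
#' @param ... Passed to [ml_tree_search()].
#' @return A list of class `"lca_rooting"`: `rooted_tree` (rooted, LCA tip
#'   included), `rooted_ingroup` (LCA tip removed, rooting preserved),
#'   `profile` (the `"ancestral_profile"`), `search`, `support` (or `NULL`),
#'   `lca_branch_length` (fitted pendant length of the LCA tip).
#' @export
lca_root <- function(aln, outgroup_label = NA, model, B = 0, seed = 1, ...) {
  ingroup_aln <- if (!is.na(outgroup_label)) {
    if (!outgroup_label %in% taxa(aln))
      stop("outgroup '", outgroup_label, "' not in alignment")
    drop_taxa(aln, outgroup_label)
  } else aln
  if (n_taxa(ingroup_aln) < 4)
    stop("LCA rooting needs >= 4 ingroup taxa for a nontrivial rooted ",
         "topology; got ", n_taxa(ingroup_aln))
  if ("LCA" %in% taxa(ingroup_aln))
    stop("alignment already contains a taxon named 'LCA'")
  star <- build_star_tree(taxa(ingroup_aln))
  profile <- marginal_asr(star, ingroup_aln, model, ...)
  seqs <- c(sequence_strings(ingroup_aln),
            LCA = profile$map_sequence)
  aln_lca <- alignment(seqs, alphabet = ingroup_aln$alphabet)
  search <- ml_tree_search(aln_lca, model, ...)
  support <- NULL
  if (B > 0)
    support <- bootstrap_support(aln_lca, model, search$best_tree, B = B,
                                 seed = seed, ...)
  rooted <- root_with_taxon(search$best_tree, "LCA")
  lca_edge <- which(rooted$edge[, 2] == match("LCA", rooted$tip.label))
  lca_len <- 2 * rooted$edge.length[lca_edge]  # rooting halved the pendant
  # dropping the surrogate tip leaves the ingroup rooted at the LCA
  # attachment point (ape splices out the degree-1 root)
  rooted_ingroup <- ape::drop.tip(rooted, "LCA")
  structure(list(rooted_tree = rooted, rooted_ingroup = rooted_ingroup,
                 profile = profile, search = search, support = support,
                 lca_branch_length = lca_len),
            class = "lca_rooting")
}

#' @export
print.lca_rooting <- function(x, ...) {
  cat("<LCA rooting>\n")
  cat("  rooted ingroup:",
      ape::write.tree(ape::ladderize(x$rooted_ingroup)), "\n")
  cat(sprintf("  LCA pendant branch length: %.5f\n", x$lca_branch_length))
  cat(sprintf("  mean MAP posterior: %.3f\n", mean(x$profile$map_posterior)))
  invisible(x)
}
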