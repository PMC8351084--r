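# The four-analysis LBA diagnosis/mitigation protocol:
#   A  full supermatrix, outgroup rooting
#   B  singleton positions pruned, outgroup dropped, 5-OTU unrooted search
#   C  as B, additionally dropping each strain in turn and re-pruning the
#      newly exposed singletons; two 4-OTU unrooted searches
#   D  LCA rooting of the unpruned ingroup (outgroup replaced by the
#      reconstructed ancestral sequence)

#' Run the long-branch-attraction protocol
#'
#' Executes the four analyses on a supermatrix: (A) exhaustive ML search on
#' the full alignment, rooted with the designated outgroup; (B) singleton
#' positions detected on the full alignment are removed together with the
#' outgroup, followed by an unrooted search on the remaining OTUs; (C)
#' starting from B's alignment, each strain of the designated pair is
#' dropped in turn, singletons newly exposed by its removal are pruned, and
#' a 4-OTU unrooted search is run (this recognizes character states private
#' to the fast lineage but shared by both strains, which analysis B cannot);
#' (D) the unpruned ingroup is rooted with a reconstructed LCA sequence via
#' [lca_root()]. Alignment lengths therefore weakly decrease from A to B to
#' C, while D retains the full length.
#'
#' @param aln The supermatrix [alignment()] (all OTUs incl. outgroup).
#' @param outgroup Outgroup taxon label.
#' @param strain_pair Character vector of the two strain tips representing
#'   the fast lineage.
#' @param model A [subst_model()]; free parameters are estimated once on
#'   the full alignment (analysis A) and reused across analyses.
#' @param B_boot Bootstrap replicates per analysis (0 = no supports).
#' @param seed Seed for bootstrap resampling.
#' @param ... Passed to [ml_tree_search()].
#' @return A list of class `"lba_protocol"` with elements `A`, `B`, `C_A`,
#'   `C_B` (named after the strain *kept*), `D`, each carrying `n_sites`,
#'   `taxa`, `tree` (`phylo`), `newick`, `support`; plus `comparison`
#'   (bipartitions gained/lost between A's and D's rooted ingroup trees),
#'   `singletons` (counts), and `flags`.
#' @export
run_lba_protocol <- function(aln, outgroup, strain_pair, model, B_boot = 0,
                             seed = 1, ...) {
  stopifnot(inherits(aln, "lca_alignment"))
  missing_roles <- setdiff(c(outgroup, strain_pair), taxa(aln))
  if (length(missing_roles) > 0)
    stop("role taxa not in alignment: ", paste(missing_roles, collapse = ", "))
  if (length(strain_pair) != 2) stop("strain_pair must name exactly 2 tips")
  flags <- character(0)

  # --- A: full alignment, outgroup-rooted -----------------------------------
  searchA <- ml_tree_search(aln, model, ...)
  modelA <- searchA$cm$model       # free parameters fitted on the full data
  rootedA <- root_with_taxon(searchA$best_tree, outgroup)
  supA <- if (B_boot > 0)
    bootstrap_support(aln, modelA, searchA$best_tree, B = B_boot,
                      seed = seed, ...) else NULL

  # --- B: prune singletons, drop outgroup -----------------------------------
  sing <- find_singleton_columns(aln)
  if (length(sing) == 0) flags <- c(flags, "no singletons removed")
  alnB <- drop_taxa(drop_columns(aln, sing), outgroup)
  searchB <- ml_tree_search(alnB, modelA, ...)
  supB <- if (B_boot > 0)
    bootstrap_support(alnB, modelA, searchB$best_tree, B = B_boot,
                      seed = seed + 1, ...) else NULL

  # --- C: additionally drop each strain, re-prune exposed singletons --------
  runC <- function(drop_strain, bseed) {
    alnC0 <- drop_taxa(alnB, drop_strain)
    singC <- find_singleton_columns(alnC0)
    alnC <- drop_columns(alnC0, singC)
    if (n_sites(alnC) == 0) {
      flags <<- c(flags, sprintf("analysis without %s: empty after pruning",
                                 drop_strain))
      return(NULL)
    }
    searchC <- ml_tree_search(alnC, modelA, ...)
    supC <- if (B_boot > 0)
      bootstrap_support(alnC, modelA, searchC$best_tree, B = B_boot,
                        seed = bseed, ...) else NULL
    analysis_entry(alnC, searchC$best_tree, supC,
                   extra = list(n_new_singletons = length(singC)))
  }
  C_A <- runC(strain_pair[2], seed + 2)   # keeps strain A
  C_B <- runC(strain_pair[1], seed + 3)   # keeps strain B

  # --- D: LCA rooting of the unpruned ingroup -------------------------------
  rooting <- lca_root(aln, outgroup, modelA, B = B_boot, seed = seed + 4, ...)

  A <- analysis_entry(aln, rootedA, supA, rooted = TRUE)
  B <- analysis_entry(alnB, searchB$best_tree, supB)
  D <- analysis_entry(drop_taxa(aln, outgroup), rooting$rooted_ingroup,
                      rooting$support, rooted = TRUE,
                      extra = list(lca_branch_length =
                                     rooting$lca_branch_length))

  # which ingroup bipartitions changed between A's and D's rooted views
  ingroup <- setdiff(taxa(aln), outgroup)
  bipA <- bipartitions(ape::keep.tip(rootedA, ingroup))
  bipD <- bipartitions(rooting$rooted_ingroup)
  comparison <- list(gained = setdiff(bipD, bipA),
                     lost = setdiff(bipA, bipD),
                     shared = intersect(bipA, bipD),
                     basal_A = basal_tips(rootedA, outgroup),
                     basal_D = basal_tips(rooting$rooted_ingroup, NULL))

  structure(list(A = A, B = B, C_A = C_A, C_B = C_B, D = D,
                 rooting = rooting, comparison = comparison,
                 singletons = list(
                   full = length(sing),
                   after_drop = c(if (!is.null(C_A)) C_A$n_new_singletons,
                                  if (!is.null(C_B)) C_B$n_new_singletons)),
                 flags = flags, outgroup = outgroup,
                 strain_pair = strain_pair, model = modelA),
            class = "lba_protocol")
}

analysis_entry <- function(aln, tree, support, rooted = FALSE, extra = list()) {
  c(list(n_sites = n_sites(aln), taxa = taxa(aln), tree = tree,
         newick = ape::write.tree(tree), rooted = rooted,
         support = if (!is.null(support)) support$support else NULL),
    extra)
}

# tip set of the basalmost (smaller) root child of a rooted tree, after
# removing `exclude` (the outgroup) from consideration
basal_tips <- function(rooted, exclude) {
  if (!is.null(exclude) && !is.na(exclude) && exclude %in% rooted$tip.label) {
    # root children are outgroup vs ingroup: descend into the ingroup side
    ntip <- length(rooted$tip.label)
    kids <- rooted$edge[rooted$edge[, 1] == ntip + 1L, 2]
    ing <- kids[kids != match(exclude, rooted$tip.label)]
    if (length(ing) != 1 || ing <= ntip) return(character(0))
    rooted <- ape::extract.clade(rooted, ing)
  }
  ntip <- length(rooted$tip.label)
  kids <- rooted$edge[rooted$edge[, 1] == ntip + 1L, 2]
  sets <- lapply(kids, function(k)
    if (k <= ntip) rooted$tip.label[k] else
      ape::extract.clade(rooted, k)$tip.label)
  sets[[which.min(lengths(sets))]]
}

#' @export
print.lba_protocol <- function(x, ...) {
  cat("<LBA protocol report>\n")
  show <- function(tag, a) {
    if (is.null(a)) { cat(sprintf("  %-4s (skipped)\n", tag)); return() }
    cat(sprintf("  %-4s %5d sites, %d OTUs%s: %s\n", tag, a$n_sites,
                length(a$taxa), if (a$rooted) " (rooted)" else "",
                a$newick))
  }
  show("A", x$A); show("B", x$B); show("C_A", x$C_A); show("C_B", x$C_B)
  show("D", x$D)
  cat("  singleton columns removed (full alignment):", x$singletons$full, "\n")
  cat("  basal ingroup lineage under outgroup rooting:",
      paste(x$comparison$basal_A, collapse = "+"), "\n")
  cat("  basal ingroup lineage under LCA rooting:    ",
      paste(x$comparison$basal_D, collapse = "+"), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Write a protocol report to disk
#'
#' A JSON manifest with per-analysis metadata plus one Newick file per
#' analysis.
#'
#' @param report An `"lba_protocol"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_protocol_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list(A = report$A, B = report$B, C_A = report$C_A,
                  C_B = report$C_B, D = report$D)
  manifest <- list(
    outgroup = report$outgroup, strain_pair = report$strain_pair,
    model = report$model$name, flags = report$flags,
    comparison = report$comparison[c("gained", "lost")],
    analyses = lapply(entries, function(a) {
      if (is.null(a)) return(NULL)
      list(n_sites = a$n_sites, taxa = a$taxa, rooted = a$rooted,
           newick = a$newick,
           support = if (!is.null(a$support)) as.list(a$support) else NULL)
    }))
  jsonlite::write_json(manifest, file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (nm in names(entries)) {
    if (is.null(entries[[nm]])) next
    ape::write.tree(entries[[nm]]$tree,
                    file.path(dir, paste0(nm, ".nwk")))
  }
  invisible(dir)
}
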