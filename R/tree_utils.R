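# Tree helpers: star trees, canonical topology forms, bipartitions, rooting.
# Trees are ape "phylo" objects throughout; unrooted binary trees carry the
# usual basal trifurcation.

#' Build a star tree
#'
#' One internal node with a pendant edge per taxon. Star trees encode no
#' resolved relationships, which makes ancestral reconstruction on them
#' agnostic to the ingroup phylogeny.
#'
#' @param taxa_labels At least 3 taxon labels.
#' @param branch_length Initial pendant edge length.
#' @return A `phylo` star tree (Nnode = 1).
#' @export
build_star_tree <- function(taxa_labels, branch_length = 0.1) {
  n <- length(taxa_labels)
  if (n < 3) stop("a star tree needs at least 3 taxa; got ", n)
  if (anyDuplicated(taxa_labels)) stop("duplicate taxon labels")
  tree <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
               edge.length = rep(branch_length, n),
               tip.label = as.character(taxa_labels), Nnode = 1L)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

#' Star-tree predicate
#'
#' @param tree A `phylo`.
#' @return `TRUE` iff the tree has exactly one internal node.
#' @export
is_star_tree <- function(tree) {
  inherits(tree, "phylo") && tree$Nnode == 1L && length(tree$tip.label) >= 3
}

assert_not_star <- function(tree, what) {
  if (is_star_tree(tree))
    stop(what, " requires a (partially) resolved tree; got a star tree, ",
         "which encodes no relationships")
  invisible(TRUE)
}

# children of each node as a list, from the edge matrix
node_children <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  ch
}

#' Canonical Newick form of a topology
#'
#' A branch-length-free Newick string that is identical for all
#' representations of the same unrooted (default) or rooted topology:
#' unrooted trees are (re)rooted on the pendant edge of the alphabetically
#' first taxon, and children are sorted by their alphabetically smallest
#' descendant. Used for deduplication and deterministic tie-breaking.
#'
#' @param tree A `phylo`.
#' @param rooted Treat the tree as rooted (do not re-root)?
#' @return A character string.
#' @export
canonical_newick <- function(tree, rooted = FALSE) {
  if (!rooted) {
    tree <- ape::unroot(tree)
    first <- sort(tree$tip.label)[1]
    tree <- ape::root(tree, outgroup = first, resolve.root = FALSE)
  }
  ch <- node_children(tree)
  ntip <- length(tree$tip.label)
  build <- function(v) {
    if (v <= ntip)
      return(list(str = tree$tip.label[v], min = tree$tip.label[v]))
    parts <- lapply(ch[[v]], build)
    mins <- vapply(parts, `[[`, "", "min")
    ord <- order(mins)
    list(str = paste0("(", paste(vapply(parts[ord], `[[`, "", "str"),
                                 collapse = ","), ")"),
         min = mins[ord][1])
  }
  root <- ntip + 1L
  paste0(build(root)$str, ";")
}

# tip label sets below each internal edge; keys are canonicalized so the two
# orientations of an unrooted split map to the same string (the side NOT
# containing the alphabetically first taxon overall).
#' Internal bipartitions of a tree
#'
#' @param tree A `phylo`.
#' @return A character vector of canonical split keys (taxa of one side,
#'   sorted, pipe-joined), one per internal edge; trivial (pendant) splits
#'   are excluded. Invariant to taxon input order and rooting.
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  all_taxa <- sort(tree$tip.label)
  ref <- all_taxa[1]
  ch <- node_children(tree)
  below <- vector("list", ntip + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  keys <- character(0)
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; v <- po[e, 2]
    if (v > ntip) {
      tips <- sort(unlist(lapply(ch[[v]], function(c2) below[[c2]])))
      below[[v]] <- tips
      if (length(tips) > 1 && length(tips) < ntip - 1) {
        side <- if (ref %in% tips) setdiff(all_taxa, tips) else tips
        keys <- c(keys, paste(sort(side), collapse = "|"))
      }
    }
  }
  # root-adjacent duplicates can arise; deduplicate
  unique(keys)
}

#' Root a tree on a tip's pendant edge
#'
#' Places the root at the midpoint of the named tip's pendant edge (a
#' display convention; the likelihood of a reversible model is unaffected).
#' The ingroup topology is unchanged.
#'
#' @param tree An unrooted `phylo` with branch lengths.
#' @param outgroup_label Tip to root on.
#' @return A rooted `phylo` whose root has two children: the outgroup tip
#'   and the ingroup subtree.
#' @export
root_with_taxon <- function(tree, outgroup_label) {
  assert_not_star(tree, "root_with_taxon()")
  if (!outgroup_label %in% tree$tip.label)
    stop("tip '", outgroup_label, "' not found in tree")
  tree <- ape::unroot(tree)
  tipn <- match(outgroup_label, tree$tip.label)
  eidx <- which(tree$edge[, 2] == tipn)
  elen <- if (is.null(tree$edge.length)) 0 else tree$edge.length[eidx]
  rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  # ape places the full pendant length on one side of the new root; split it
  root <- length(rooted$tip.label) + 1L
  redges <- which(rooted$edge[, 1] == root)
  if (!is.null(rooted$edge.length) && length(redges) == 2) {
    tipedge <- redges[rooted$edge[redges, 2] == match(outgroup_label,
                                                      rooted$tip.label)]
    othedge <- setdiff(redges, tipedge)
    tot <- sum(rooted$edge.length[redges])
    rooted$edge.length[tipedge] <- tot / 2
    rooted$edge.length[othedge] <- tot / 2
  }
  rooted
}

#' Test whether a set of tips is the basalmost lineage of a rooted tree
#'
#' `TRUE` iff one of the root's two children subtends exactly `tips` — i.e.
#' the lineage is sister to everything else in the tree.
#'
#' @param rooted A rooted `phylo`.
#' @param tips Character vector of tip labels forming the candidate lineage.
#' @return Logical.
#' @export
is_basal_lineage <- function(rooted, tips) {
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  if (length(kids) != 2) stop("tree is not rooted (root degree != 2)")
  for (k in kids) {
    sub <- if (k <= ntip) rooted$tip.label[k] else
      ape::extract.clade(rooted, k)$tip.label
    if (setequal(sub, tips)) return(TRUE)
  }
  FALSE
}

#' Split and clade membership tests
#'
#' `has_bipartition()` asks whether an (unrooted) tree contains the internal
#' split separating `tips` from the rest; the split is canonicalized, so
#' either side may be given. `has_clade()` asks whether a rooted tree
#' contains a node whose descendant tip set is exactly `tips` (rooted
#' monophyly).
#'
#' @param tree A `phylo` (rooted for `has_clade()`).
#' @param tips Character vector of tip labels.
#' @return Logical.
#' @export
has_bipartition <- function(tree, tips) {
  all_taxa <- sort(tree$tip.label)
  if (!all(tips %in% all_taxa)) stop("unknown tip labels")
  side <- if (all_taxa[1] %in% tips) setdiff(all_taxa, tips) else tips
  paste(sort(side), collapse = "|") %in% bipartitions(tree)
}

#' @rdname has_bipartition
#' @export
has_clade <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  if (!all(tips %in% tree$tip.label)) stop("unknown tip labels")
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    if (setequal(ape::extract.clade(tree, v)$tip.label, tips)) return(TRUE)
  }
  length(tips) == 1L && tips %in% tree$tip.label
}

# (2n-5)!! — the number of unrooted binary topologies on n >= 3 taxa
double_factorial_topologies <- function(n) {
  if (n < 3) stop("n must be >= 3")
  if (n == 3) return(1)
  prod(seq(3, 2 * n - 5, by = 2))
}
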