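# Sequence-evolution simulator: site-wise i.i.d. Markov simulation along a
# tree with a fresh discrete-gamma rate per site (and an invariant-site
# class), plus a canned long-branch-attraction scenario generator that
# mirrors a deep-split ingroup with a near-identical strain pair, one
# fast-evolving lineage and a very distant outgroup.

# run code under a temporary RNG state so simulation is a pure function of
# its seed and never perturbs the caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation specification
#'
#' @param tree A rooted (or basal-multifurcating) `phylo` with branch
#'   lengths in expected substitutions/site.
#' @param model A concrete [subst_model()] (all parameters fixed; `+F` is
#'   not meaningful for simulation, supply explicit frequencies instead).
#' @param n_sites Total alignment length, >= 1.
#' @param n_genes Number of contiguous gene partitions the sites are split
#'   into (near-equal lengths).
#' @param seed Integer seed; the simulation is a pure function of the spec.
#' @return An object of class `"sim_spec"`.
#' @export
simulation_spec <- function(tree, model, n_sites, n_genes = 1L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  if (is.null(tree$tip.label) || length(tree$tip.label) == 0)
    stop("tree has no taxa")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!is.numeric(n_sites) || n_sites < 1) stop("n_sites must be >= 1")
  if (n_genes < 1 || n_genes > n_sites)
    stop("n_genes must be in 1..n_sites")
  if (model$freqs_mode == "empirical")
    stop("simulation needs explicit frequencies; +F is an inference-side ",
         "device (use frequencies= in subst_model())")
  if (model$has_gamma && is.na(model$alpha))
    stop("simulation model must fix alpha")
  if (model$has_inv && is.na(model$p_inv))
    stop("simulation model must fix p_inv")
  structure(list(tree = tree, model = model, n_sites = as.integer(n_sites),
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate an alignment along a tree
#'
#' Site-wise i.i.d. simulation: each site draws an invariant flag (with
#' probability `p_inv`) and otherwise a discrete-gamma rate category, a root
#' state from the equilibrium frequencies, and then evolves along each
#' branch by the model's transition probabilities. The same spec (including
#' seed) always produces bit-identical output. Output is gapless; curated
#' alignments are the intended analysis input, so indels are out of scope.
#'
#' @param spec A [simulation_spec()].
#' @return An [alignment()], with attributes `root_seq` (the true root
#'   sequence as a string — kept for benchmarking ancestral reconstruction),
#'   `partition` (gene partition data frame when `n_genes > 1`), and
#'   `sim_spec`.
#' @examples
#' tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
#' aln <- simulate_alignment(simulation_spec(tr, subst_model("JC"), 100))
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  cm <- resolve_model(spec$model)
  tree <- ape::reorder.phylo(spec$tree, "postorder")
  ns <- length(cm$pi)
  L <- spec$n_sites
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L

  out <- with_seed(spec$seed, {
    inv <- if (cm$p_inv > 0) runif(L) < cm$p_inv else rep(FALSE, L)
    nc <- length(cm$rates)
    cat_idx <- sample.int(nc, L, replace = TRUE)
    rate <- ifelse(inv, 0, cm$rates[cat_idx])
    states <- matrix(0L, nn, L)
    states[root, ] <- sample.int(ns, L, replace = TRUE, prob = cm$pi)
    # preorder: parents before children
    for (e in rev(seq_len(nrow(tree$edge)))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]; t <- tree$edge.length[e]
      ps <- states[p, ]
      cs <- ps                         # zero evolution: copy parent
      if (t > 0) {
        for (k in seq_len(nc)) {
          P <- transition_probabilities(cm$rm, t, cm$rates[k])
          for (s in seq_len(ns)) {
            idx <- which(!inv & cat_idx == k & ps == s)
            if (length(idx) > 0)
              cs[idx] <- sample.int(ns, length(idx), replace = TRUE,
                                    prob = P[s, ])
          }
        }
      }
      states[v, ] <- cs
    }
    list(states = states)
  })

  st <- alphabet_states(spec$model$alphabet)
  seqmat <- matrix(st[out$states[seq_len(nt), ]], nrow = nt,
                   dimnames = list(tree$tip.label, NULL))
  aln <- structure(list(seq = seqmat, alphabet = spec$model$alphabet),
                   class = "lca_alignment")
  attr(aln, "root_seq") <- paste(st[out$states[root, ]], collapse = "")
  if (spec$n_genes > 1) {
    cuts <- round(seq(0, L, length.out = spec$n_genes + 1))
    lens <- as.integer(diff(cuts))
    end <- cumsum(lens)
    attr(aln, "partition") <- data.frame(
      gene = sprintf("gene%03d", seq_len(spec$n_genes)),
      start = end - lens + 1L, end = end, length = lens,
      stringsAsFactors = FALSE)
  }
  attr(aln, "sim_spec") <- spec
  aln
}

#' Long-branch-attraction scenario specification
#'
#' Encodes the canonical deep-split LBA situation: four ingroup lineages of
#' which one evolves much faster than the others and is represented by two
#' near-identical strain sequences (a cherry subtending the fast lineage),
#' plus a highly divergent outgroup attached at the ingroup root. Default
#' branch lengths make the fast lineage's branch an order of magnitude
#' longer than its neighbours and the outgroup twice as long again.
#'
#' @param short_branch Length of ordinary ingroup branches.
#' @param long_branch Length of the fast lineage's branch; must exceed
#'   `short_branch`.
#' @param strain_divergence Total divergence between the two strain tips;
#'   must be well below `short_branch` (enforced: `< short_branch / 10`).
#' @param outgroup_distance Pendant length of the outgroup; must exceed
#'   `long_branch`.
#' @param model Simulation model (default LG with 4 gamma categories,
#'   shape 1).
#' @param n_sites Alignment length (default 5000).
#' @param seed Integer seed.
#' @param ingroup_topology Optional rooted 4-lineage `phylo` (no branch
#'   lengths needed) over the lineage names; defaults to
#'   `((acantho,seison),(bdelloid,monogonont))` with `seison` the fast
#'   lineage carrying strains `seison_A`/`seison_B`.
#' @param fast_lineage Name of the lineage carrying the long branch and the
#'   strain pair.
#' @return An object of class `"lba_spec"`.
#' @export
lba_scenario_spec <- function(short_branch = 0.1, long_branch = 1.0,
                              strain_divergence = 0.002,
                              outgroup_distance = 2.0,
                              model = subst_model("LG+G4", alpha = 1),
                              n_sites = 5000, seed = 1L,
                              ingroup_topology = NULL,
                              fast_lineage = "seison") {
  if (!(long_branch > short_branch))
    stop("invariant violated: long_branch (", long_branch,
         ") must exceed short_branch (", short_branch, ")")
  if (!(outgroup_distance > long_branch))
    stop("invariant violated: outgroup_distance (", outgroup_distance,
         ") must exceed long_branch (", long_branch, ")")
  if (!(strain_divergence < short_branch / 10))
    stop("invariant violated: strain_divergence (", strain_divergence,
         ") must be well below short_branch (< ", short_branch / 10, ")")
  if (strain_divergence < 0) stop("invariant violated: strain_divergence < 0")
  if (is.null(ingroup_topology))
    ingroup_topology <- ape::read.tree(
      text = "((acantho,seison),(bdelloid,monogonont));")
  if (!fast_lineage %in% ingroup_topology$tip.label)
    stop("fast_lineage '", fast_lineage, "' not in ingroup topology")
  if (length(ingroup_topology$tip.label) != 4)
    stop("ingroup_topology must have exactly 4 lineages")
  structure(list(short_branch = short_branch, long_branch = long_branch,
                 strain_divergence = strain_divergence,
                 outgroup_distance = outgroup_distance, model = model,
                 n_sites = as.integer(n_sites), seed = as.integer(seed),
                 ingroup_topology = ingroup_topology,
                 fast_lineage = fast_lineage),
            class = "lba_spec")
}

#' Generate a long-branch-attraction scenario
#'
#' Builds the generating tree from an [lba_scenario_spec()] — ordinary
#' lineages get `short_branch`, the fast lineage gets `long_branch` and is
#' replaced by a cherry of two strain tips (`<fast>_A`, `<fast>_B`, each at
#' `strain_divergence / 2`), and the outgroup is attached at the ingroup
#' root at `outgroup_distance` — then simulates an alignment on it.
#'
#' @param spec An [lba_scenario_spec()].
#' @return A list: `alignment` (6 OTUs), `ingroup_alignment` (outgroup
#'   removed), `tree` (generating tree with branch lengths), `true_rooted_ingroup`
#'   (the generating rooted ingroup topology with the strain cherry, for
#'   scoring), `root_seq`, `strain_pair`, `outgroup`, `spec`.
#' @export
make_lba_scenario <- function(spec) {
  stopifnot(inherits(spec, "lba_spec"))
  ig <- spec$ingroup_topology
  fast <- spec$fast_lineage
  sb <- spec$short_branch
  # rooted ingroup with branch lengths; fast lineage -> strain cherry
  lens_newick <- function(with_out) {
    ch <- node_children(ig)
    ntip <- length(ig$tip.label)
    build <- function(v) {
      if (v <= ntip) {
        lab <- ig$tip.label[v]
        if (lab == fast) {
          d2 <- spec$strain_divergence / 2
          return(sprintf("(%s_A:%g,%s_B:%g):%g", fast, d2, fast, d2,
                         spec$long_branch))
        }
        return(sprintf("%s:%g", lab, sb))
      }
      kids <- paste(vapply(ch[[v]], build, ""), collapse = ",")
      sprintf("(%s):%g", kids, sb)
    }
    root <- ntip + 1L
    kids <- paste(vapply(node_children(ig)[[root]], build, ""),
                  collapse = ",")
    if (with_out)
      sprintf("(%s,outgroup:%g);", kids, spec$outgroup_distance)
    else sprintf("(%s);", kids)
  }
  tree_full <- ape::read.tree(text = lens_newick(TRUE))
  true_rooted <- ape::read.tree(text = lens_newick(FALSE))
  sim <- simulation_spec(tree_full, spec$model, spec$n_sites, seed = spec$seed)
  aln <- simulate_alignment(sim)
  list(alignment = aln,
       ingroup_alignment = drop_taxa(aln, "outgroup"),
       tree = tree_full,
       true_rooted_ingroup = true_rooted,
       root_seq = attr(aln, "root_seq"),
       strain_pair = paste0(fast, c("_A", "_B")),
       outgroup = "outgroup",
       spec = spec)
}
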