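# Supermatrix construction and the alignment-editing operations used by the
# LBA protocol: singleton-position detection/removal and taxon deletion.
# All column coordinates exposed to users are 1-based and inclusive.

#' Concatenate per-gene alignments into a supermatrix
#'
#' All gene alignments must share an identical taxon set (any order) and the
#' same alphabet. Sequences are concatenated gene by gene in the order given;
#' the returned partition map records, for every gene, the 1-based inclusive
#' column interval it occupies in the supermatrix.
#'
#' @param genes A list of [alignment()] objects, optionally named.
#' @return A list with elements `alignment` (the supermatrix) and `partition`
#'   (a data frame with columns `gene`, `start`, `end`, `length`).
#' @examples
#' g1 <- alignment(c(a = "ACGTACG", b = "ACGTACG", c = "ACGAACG"), "nt")
#' g2 <- alignment(c(b = "TTTTT", a = "TTTTA", c = "TTGTA"), "nt")
#' sm <- concatenate_genes(list(gene1 = g1, gene2 = g2))
#' n_sites(sm$alignment)  # 12
#' @export
concatenate_genes <- function(genes) {
  if (!is.list(genes) || length(genes) == 0)
    stop("genes must be a non-empty list of alignments")
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    names(genes) <- sprintf("gene%03d", seq_along(genes))
  ref <- genes[[1]]
  ref_taxa <- sort(taxa(ref))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (!inherits(g, "lca_alignment")) stop("element ", i, " is not an alignment")
    if (g$alphabet != ref$alphabet)
      stop("alphabet mismatch in gene '", names(genes)[i], "': ",
           g$alphabet, " vs ", ref$alphabet)
    if (!identical(sort(taxa(g)), ref_taxa)) {
      only_ref <- setdiff(ref_taxa, taxa(g))
      only_g <- setdiff(taxa(g), ref_taxa)
      stop("taxon set mismatch in gene '", names(genes)[i], "': missing {",
           paste(only_ref, collapse = ", "), "}, extra {",
           paste(only_g, collapse = ", "), "}")
    }
  }
  ord <- taxa(ref)
  mats <- lapply(genes, function(g) g$seq[ord, , drop = FALSE])
  sm <- do.call(cbind, mats)
  rownames(sm) <- ord
  lens <- vapply(genes, n_sites, 0L)
  end <- cumsum(lens)
  partition <- data.frame(gene = names(genes),
                          start = end - lens + 1L, end = end, length = lens,
                          row.names = NULL, stringsAsFactors = FALSE)
  list(alignment = structure(list(seq = sm, alphabet = ref$alphabet),
                             class = "lca_alignment"),
       partition = partition)
}

#' Detect singleton (private-character) columns
#'
#' A column is a singleton position if at least one non-gap, non-missing
#' state in it occurs in exactly one sequence. Gap and missing symbols are
#' transparent: they are never private characters themselves and never
#' prevent another state from being private. Note that a state carried by
#' both members of a near-identical strain pair is *not* private, which is
#' exactly why taxon-deletion variants of the analysis exist.
#'
#' @param aln An [alignment()].
#' @return A sorted integer vector of 1-based column indices (possibly empty).
#' @examples
#' aln <- alignment(c(w = "AAAA", x = "ACA-", y = "ACTA", z = "ACTA"), "nt")
#' find_singleton_columns(aln)
#' @export
find_singleton_columns <- function(aln) {
  stopifnot(inherits(aln, "lca_alignment"))
  if (n_sites(aln) == 0L) return(integer(0))
  codes <- alignment_codes(aln)
  ns <- length(alphabet_states(aln$alphabet))
  # counts[s, j] = number of sequences with state s at column j
  counts <- vapply(seq_len(ns), function(s) colSums(codes == s),
                   numeric(n_sites(aln)))
  if (n_sites(aln) == 1L) counts <- matrix(counts, nrow = 1L)
  which(apply(counts == 1, 1, any))
}

#' Per-column singleton report
#'
#' @param aln An [alignment()].
#' @return A data frame with one row per private character: `column`
#'   (1-based), `state`, `taxon` (its unique carrier).
#' @export
singleton_report <- function(aln) {
  cols <- find_singleton_columns(aln)
  out <- list()
  for (j in cols) {
    col <- aln$seq[, j]
    keep <- !(col %in% missing_chars(aln$alphabet))
    tab <- table(col[keep])
    for (s in names(tab)[tab == 1]) {
      out[[length(out) + 1L]] <- data.frame(
        column = j, state = s, taxon = names(col)[keep & col == s][1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(column = integer(0), state = character(0),
                      taxon = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Remove columns or taxa from an alignment
#'
#' Order of surviving columns and taxa is preserved. If a partition map is
#' supplied to `drop_columns()`, it is re-indexed so that each gene's
#' interval covers its surviving columns (genes may end up with length 0).
#'
#' @param aln An [alignment()].
#' @param columns 1-based column indices to remove.
#' @param partition Optional partition data frame as returned by
#'   [concatenate_genes()].
#' @param taxa_to_drop Character vector of taxon labels to remove.
#' @return An [alignment()]; for `drop_columns()` with a partition, a list
#'   with elements `alignment` and `partition`.
#' @export
drop_columns <- function(aln, columns, partition = NULL) {
  stopifnot(inherits(aln, "lca_alignment"))
  columns <- unique(as.integer(columns))
  if (length(columns) > 0 &&
      (any(is.na(columns)) || any(columns < 1) || any(columns > n_sites(aln))))
    stop("column indices out of range 1..", n_sites(aln))
  keep <- setdiff(seq_len(n_sites(aln)), columns)
  if (length(keep) == 0L)
    message("drop_columns: all ", n_sites(aln), " columns removed; ",
            "result is a length-0 alignment")
  out <- structure(list(seq = aln$seq[, keep, drop = FALSE],
                        alphabet = aln$alphabet), class = "lca_alignment")
  if (is.null(partition)) return(out)
  newlen <- vapply(seq_len(nrow(partition)), function(i) {
    sum(keep >= partition$start[i] & keep <= partition$end[i])
  }, 0L)
  end <- cumsum(newlen)
  list(alignment = out,
       partition = data.frame(gene = partition$gene, start = end - newlen + 1L,
                              end = end, length = newlen,
                              stringsAsFactors = FALSE))
}

#' @rdname drop_columns
#' @export
drop_taxa <- function(aln, taxa_to_drop) {
  stopifnot(inherits(aln, "lca_alignment"))
  unknown <- setdiff(taxa_to_drop, taxa(aln))
  if (length(unknown) > 0)
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  keep <- setdiff(taxa(aln), taxa_to_drop)
  if (length(keep) == 0L) stop("cannot drop every taxon")
  structure(list(seq = aln$seq[keep, , drop = FALSE], alphabet = aln$alphabet),
            class = "lca_alignment")
}

#' Remove singleton positions
#'
#' Single-pass by default, matching a one-shot alignment edit. Removing
#' singleton columns can expose new singletons (and, in gapped alignments,
#' the gap-transparency rule can do the same), so the operation is *not*
#' idempotent; set `until_stable = TRUE` to iterate to a fixed point.
#'
#' @param aln An [alignment()].
#' @param until_stable Iterate until no singleton columns remain?
#' @return A list: `alignment` (pruned), `removed` (1-based indices removed
#'   from the original alignment), `report` (per-character report of the
#'   first pass), `passes`.
#' @export
prune_singletons <- function(aln, until_stable = FALSE) {
  report <- singleton_report(aln)
  removed <- find_singleton_columns(aln)
  cur <- drop_columns(aln, removed)
  passes <- 1L
  if (until_stable) {
    orig_idx <- setdiff(seq_len(n_sites(aln)), removed)
    repeat {
      s <- find_singleton_columns(cur)
      if (length(s) == 0L) break
      removed <- sort(c(removed, orig_idx[s]))
      orig_idx <- orig_idx[-s]
      cur <- drop_columns(cur, s)
      passes <- passes + 1L
    }
  }
  list(alignment = cur, removed = removed, report = report, passes = passes)
}
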