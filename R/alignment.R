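#' @useDynLib lcaroot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize optim runif qgamma pgamma setNames
#' @importFrom utils write.table head
"_PACKAGE"

# Alphabet definitions. Amino-acid states follow the PAML/LG ordering so that
# shipped exchangeability tables can be used without reindexing.
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
NT_STATES <- c("A", "C", "G", "T")

alphabet_states <- function(alphabet) {
  switch(alphabet, aa = AA_STATES, nt = NT_STATES,
         stop("unknown alphabet: ", alphabet))
}

missing_chars <- function(alphabet) {
  switch(alphabet, aa = c("-", "X", "?", "*"), nt = c("-", "N", "?"),
         stop("unknown alphabet: ", alphabet))
}

#' Multiple sequence alignment container
#'
#' A light container for a (gap-aware) multiple sequence alignment over a
#' declared alphabet. Sequences are stored as a character matrix with one row
#' per taxon; columns are alignment positions (1-based, the R convention,
#' which is also used in all reports).
#'
#' @param sequences Either a named character vector of sequence strings (one
#'   per taxon) or a character matrix of single residues with row names.
#' @param alphabet `"aa"` (20 amino-acid states) or `"nt"` (4 nucleotide
#'   states). Gap (`-`) and missing (`X`/`N`, `?`) symbols are allowed and
#'   treated as missing data throughout.
#' @return An object of class `"lca_alignment"`.
#' @examples
#' aln <- alignment(c(t1 = "ACGT", t2 = "ACGA"), alphabet = "nt")
#' n_sites(aln)
#' @export
alignment <- function(sequences, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must be uniquely named")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1)
      stop("all sequences must have equal length; got lengths ",
           paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, strsplit(sequences, ""))
    if (length(sequences) == 1L || lens[1] == 0L)
      mat <- matrix(unlist(strsplit(sequences, "")), nrow = length(sequences),
                    byrow = TRUE, dimnames = list(names(sequences), NULL))
    rownames(mat) <- names(sequences)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("taxon labels must be present and unique")
  if (nrow(mat) == 0L) stop("alignment must contain at least one taxon")
  mat[] <- toupper(mat)
  ok <- c(alphabet_states(alphabet), missing_chars(alphabet))
  bad <- setdiff(unique(as.vector(mat)), ok)
  if (length(bad) > 0)
    stop("residues outside declared alphabet '", alphabet, "': ",
         paste(bad, collapse = " "))
  structure(list(seq = mat, alphabet = alphabet), class = "lca_alignment")
}

#' @export
print.lca_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d taxa x %d sites (%s)\n",
              n_taxa(x), n_sites(x),
              if (x$alphabet == "aa") "amino acid" else "nucleotide"))
  shown <- head(taxa(x), 6)
  for (t in shown) {
    s <- paste(x$seq[t, seq_len(min(50, n_sites(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", t, s, if (n_sites(x) > 50) "..." else ""))
  }
  if (n_taxa(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Alignment dimensions and labels
#'
#' @param aln An [alignment()].
#' @return `n_taxa()`/`n_sites()` return integers; `taxa()` the taxon labels;
#'   `sequence_strings()` a named character vector of full sequences.
#' @export
n_taxa <- function(aln) nrow(aln$seq)

#' @rdname n_taxa
#' @export
n_sites <- function(aln) ncol(aln$seq)

#' @rdname n_taxa
#' @export
taxa <- function(aln) rownames(aln$seq)

#' @rdname n_taxa
#' @export
sequence_strings <- function(aln) {
  setNames(apply(aln$seq, 1, paste, collapse = ""), taxa(aln))
}

# integer codes: 1..n_states, 0 for gap/missing
alignment_codes <- function(aln) {
  st <- alphabet_states(aln$alphabet)
  codes <- match(aln$seq, st, nomatch = 0L)
  matrix(codes, nrow = n_taxa(aln), dimnames = dimnames(aln$seq))
}

#' Read and write alignments (FASTA, relaxed PHYLIP)
#'
#' FASTA is written wrapped at 60 residues per line. PHYLIP I/O uses the
#' relaxed sequential layout (whitespace-separated labels of any length up to
#' 250 characters). Round-trips are lossless.
#'
#' @param file Path.
#' @param alphabet `"aa"` or `"nt"`.
#' @param aln An [alignment()].
#' @param width Residues per FASTA line.
#' @return `read_*` return an [alignment()]; `write_*` return the path,
#'   invisibly.
#' @export
read_fasta_alignment <- function(file, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers found in ", file)
  idx <- cumsum(hdr)
  labs <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  alignment(setNames(seqs, labs), alphabet)
}

#' @rdname read_fasta_alignment
#' @export
write_fasta_alignment <- function(aln, file, width = 60) {
  con <- file(file, "w")
  on.exit(close(con))
  for (t in taxa(aln)) {
    writeLines(paste0(">", t), con)
    s <- paste(aln$seq[t, ], collapse = "")
    starts <- seq(1, max(1, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(file)
}

#' @rdname read_fasta_alignment
#' @export
read_phylip_alignment <- function(file, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hd <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hd) != 2) stop("malformed PHYLIP header in ", file)
  ntax <- hd[1]
  if (length(lines) < ntax + 1) stop("PHYLIP file truncated: ", file)
  labs <- character(ntax); seqs <- character(ntax)
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labs[i] <- parts[1]
    seqs[i] <- paste(parts[-1], collapse = "")
  }
  if (any(nchar(seqs) != hd[2]))
    stop("PHYLIP sequence length disagrees with header in ", file)
  alignment(setNames(seqs, labs), alphabet)
}

#' @rdname read_fasta_alignment
#' @export
write_phylip_alignment <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", n_taxa(aln), n_sites(aln)), con)
  s <- sequence_strings(aln)
  writeLines(sprintf("%s  %s", format(names(s)), s), con)
  invisible(file)
}

#' Convert to a phangorn phyDat object
#'
#' Useful for interoperating with the wider phylogenetics ecosystem and for
#' independent cross-checks.
#'
#' @param aln An [alignment()].
#' @return A [phangorn::phyDat] object.
#' @export
as_phyDat <- function(aln) {
  type <- if (aln$alphabet == "aa") "AA" else "DNA"
  phangorn::phyDat(aln$seq, type = type)
}
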