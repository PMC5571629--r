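# 16S marker-sequence utilities: V4 sub-region extraction by degenerate
# primer matching, and a pairwise percent-identity matrix for pre-aligned
# sequences.

#' The 515F/806R V4 primer pair
#'
#' IUPAC-degenerate primers commonly used to amplify the 16S V4 region
#' (515FB forward, 806RB reverse).
#'
#' @return List with `forward` and `reverse` IUPAC strings.
#' @export
v4_primers <- function() {
  list(forward = "GTGYCAGCMGCCGCGGTAA", reverse = "GGACTACNVGGGTWTCTAAT")
}

check_iupac <- function(x, what) {
  if (grepl("[^ACGTRYSWKMBDHVN]", x))
    stop(what, " primer contains non-IUPAC characters")
  x
}

#' Extract the V4 sub-region between degenerate primers
#'
#' Finds the first match of the forward primer and, downstream of it, the
#' first match of the reverse complement of the reverse primer; returns
#' the region between them with both primer sites excluded. Degenerate
#' IUPAC codes in the primers match their constituent bases.
#'
#' @param sequences Character vector of nucleotide sequences (A/C/G/T/N).
#' @param primers List with `forward` and `reverse` IUPAC strings
#'   (default [v4_primers()]).
#' @return Character vector of extracted sub-sequences.
#' @export
extract_v4 <- function(sequences, primers = v4_primers()) {
  fwd <- Biostrings::DNAString(check_iupac(primers$forward, "forward"))
  rev_rc <- Biostrings::reverseComplement(
    Biostrings::DNAString(check_iupac(primers$reverse, "reverse")))
  vapply(sequences, function(s) {
    subj <- Biostrings::DNAString(s)
    mf <- Biostrings::matchPattern(fwd, subj, fixed = FALSE)
    if (length(mf) == 0L) stop("forward primer not found in sequence")
    f_end <- Biostrings::end(mf)[1]
    mr <- Biostrings::matchPattern(rev_rc, subj, fixed = FALSE)
    mr_ok <- which(Biostrings::start(mr) > f_end)
    if (length(mr) == 0L || length(mr_ok) == 0L)
      stop("reverse primer not found downstream of the forward primer")
    r_start <- Biostrings::start(mr)[mr_ok[1]]
    if (r_start <= f_end + 1L) return("")
    as.character(Biostrings::subseq(subj, f_end + 1L, r_start - 1L))
  }, character(1), USE.NAMES = !is.null(names(sequences)))
}

#' Pairwise percent-identity matrix of aligned sequences
#'
#' For each sequence pair, identity is 100 times the fraction of matching
#' positions among the columns where neither sequence has a gap
#' (`-` or `.`). A pair with no gap-free overlap is reported `NA`, not 0.
#'
#' @param aligned Named character vector of equal-length aligned
#'   sequences.
#' @return Symmetric numeric matrix of percentages, diagonal 100.
#' @export
identity_matrix <- function(aligned) {
  n <- length(aligned)
  stopifnot(n >= 1L)
  L <- unique(nchar(aligned))
  if (length(L) != 1L) stop("aligned sequences must all have the same length")
  chars <- lapply(aligned, function(s) strsplit(toupper(s), "")[[1]])
  nm <- names(aligned) %||% sprintf("seq%d", seq_len(n))
  M <- matrix(100, n, n, dimnames = list(nm, nm))
  gap <- c("-", ".")
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      a <- chars[[i]]; b <- chars[[j]]
      ok <- !(a %in% gap) & !(b %in% gap)
      M[i, j] <- M[j, i] <- if (!any(ok)) NA_real_ else
        100 * mean(a[ok] == b[ok])
    }
  }
  M
}
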