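# Global protein alignment and percent identity.
#
# Scoring follows the classical setup for whole-protein comparison: BLOSUM62,
# affine gaps with opening penalty 11 and extension penalty 1 (the first gap
# residue costs 12, each further residue 1), terminal gaps penalized (true
# global alignment). X is tolerated and scores 0 against anything.

.seqsim_env <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(.seqsim_env$blosum62)) {
    mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment())[1], envir = environment())
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .seqsim_env$blosum62 <- mat
  }
  .seqsim_env$blosum62
}

check_protein <- function(seq, arg) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop(arg, " must be a single non-empty protein sequence")
  }
  letters_ok <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!(ch %in% letters_ok))
  if (length(bad)) {
    stop("illegal amino-acid character '", ch[bad[1]], "' at position ",
         bad[1], " of ", arg)
  }
  paste(ch, collapse = "")
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch alignment under BLOSUM62 with affine gap penalties
#' (opening 11, extension 1; a length-L gap costs `11 + L`). Terminal gaps
#' are penalized. Ties between equal-scoring alignments are broken
#' deterministically by the underlying dynamic program.
#'
#' @param seq_a,seq_b protein sequences (20-letter alphabet; `X` allowed and
#'   scored 0 against everything).
#' @return an object of class `alignment_result`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `matches`
#'   (identical aligned residue pairs) and `length` (alignment columns).
#' @export
global_align <- function(seq_a, seq_b) {
  seq_a <- check_protein(seq_a, "seq_a")
  seq_b <- check_protein(seq_b, "seq_b")
  sub <- blosum62_matrix()
  res <- .nw_align(seq_a, seq_b, sub, rownames(sub), 11, 1)
  structure(res[c("aligned_a", "aligned_b", "score", "matches", "length")],
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %.1f, identity %.3f (%d/%d)\n",
              x$score, x$matches / x$length, x$matches, x$length))
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' The number of matching residues divided by the length of the alignment;
#' gap columns count in the denominator and no coverage filter is applied.
#'
#' @param alignment an `alignment_result` from [global_align()].
#' @return fraction in `[0, 1]`.
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "alignment_result"))
  alignment$matches / alignment$length
}

#' Align every pair in a table and compute identity and divergence
#'
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param proteins named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param cds optional named character vector (or `DNAStringSet`) of coding
#'   sequences; when supplied, Nei-Gojobori `dN`, `dS` and `dN/dS` are added.
#' @return `pairs` with columns `identity`, and if `cds` given `dN`, `dS`,
#'   `dn_ds`, `ds_unreliable`.
#' @export
align_pairs <- function(pairs, proteins, cds = NULL) {
  proteins <- char_with_names(proteins)
  if (!is.null(cds)) cds <- char_with_names(cds)
  n <- nrow(pairs)
  identity <- dn <- ds <- dnds <- rep(NA_real_, n)
  unrel <- rep(NA, n)
  have <- pairs$gene_a %in% names(proteins) & pairs$gene_b %in% names(proteins)
  for (k in which(have)) {
    a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
    aln <- global_align(proteins[[a]], proteins[[b]])
    identity[k] <- percent_identity(aln)
    if (!is.null(cds) && !is.na(cds[a]) && !is.na(cds[b])) {
      d <- estimate_divergence(cds[[a]], cds[[b]], aln)
      dn[k] <- d$dN; ds[k] <- d$dS; dnds[k] <- d$dn_ds
      unrel[k] <- d$ds_unreliable
    }
  }
  pairs$identity <- identity
  if (!is.null(cds)) {
    pairs$dN <- dn; pairs$dS <- ds; pairs$dn_ds <- dnds
    pairs$ds_unreliable <- unrel
  }
  pairs
}
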