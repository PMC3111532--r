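# Probe-to-gene mapping and two-step z-score normalization of
# tissue-expression matrices.

#' Map probesets to genes by exact probe matching
#'
#' A probeset is retained iff every one of its probes exactly
#' substring-matches at least one transcript of exactly one gene, and no
#' probe matches a transcript of any other gene. Matching is on the given
#' strand by default; `both_strands = TRUE` also searches the reverse
#' complement of each probe.
#'
#' @param probes named character vector of probe sequences; names are
#'   `probeset:index` (e.g. `"PS0001:7"`).
#' @param transcripts named character vector of transcript sequences; names
#'   are `gene|transcript` (e.g. `"G12|G12.t1"`).
#' @param both_strands also match reverse-complemented probes.
#' @return data frame with columns `probeset_id`, `gene_id` (retained sets
#'   only); attribute `"rejections"` is a data frame of dropped probesets
#'   with a reason (`"unmatched_probe"` or `"multiple_genes"`).
#' @export
map_probes_to_genes <- function(probes, transcripts, both_strands = FALSE) {
  probes <- char_with_names(probes)
  transcripts <- char_with_names(transcripts)
  if (is.null(names(probes)) || is.null(names(transcripts))) {
    stop("probes and transcripts must be named")
  }
  tx_gene <- sub("\\|.*$", "", names(transcripts))
  probeset <- sub(":[^:]*$", "", names(probes))
  # genes hit by each probe
  probe_hits <- probe_gene_hits(probes, transcripts, tx_gene)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(probes)))
    rc_hits <- probe_gene_hits(rc, transcripts, tx_gene)
    probe_hits <- mapply(function(a, b) unique(c(a, b)), probe_hits, rc_hits,
                         SIMPLIFY = FALSE)
  }
  out <- list(); rej <- list()
  for (ps in unique(probeset)) {
    hits <- probe_hits[probeset == ps]
    if (any(lengths(hits) == 0L)) {
      rej[[ps]] <- "unmatched_probe"
    } else if (length(unique(unlist(hits))) != 1L) {
      rej[[ps]] <- "multiple_genes"
    } else {
      out[[ps]] <- unlist(hits)[1]
    }
  }
  map <- data.frame(probeset_id = names(out),
                    gene_id = unlist(out, use.names = FALSE),
                    stringsAsFactors = FALSE)
  rejections <- data.frame(probeset_id = names(rej),
                           reason = unlist(rej, use.names = FALSE),
                           stringsAsFactors = FALSE)
  attr(map, "rejections") <- rejections
  map
}

# coerce XStringSet or character to character, keeping names
char_with_names <- function(x) {
  if (is.character(x)) return(x)
  stats::setNames(as.character(x), names(x))
}

probe_gene_hits <- function(probes, transcripts, tx_gene) {
  widths <- nchar(probes)
  txset <- Biostrings::DNAStringSet(transcripts)
  if (length(unique(widths)) == 1L && length(probes) > 1L) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes))
    hits_per_tx <- Biostrings::vwhichPDict(pd, txset)
    res <- vector("list", length(probes))
    for (t in seq_along(hits_per_tx)) {
      for (p in hits_per_tx[[t]]) res[[p]] <- c(res[[p]], tx_gene[t])
    }
    lapply(res, unique)
  } else {
    lapply(probes, function(p) {
      unique(tx_gene[Biostrings::vcountPattern(p, txset) > 0])
    })
  }
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Two-step z-score normalization of an expression matrix
#'
#' Step 1 standardizes each tissue column: `t_ij = (s_ij - mu_j) / sigma_j`,
#' forcing every tissue to mean 0 and standard deviation 1 across probesets.
#' Step 2 then standardizes each probeset row of `t`:
#' `n_ij = (t_ij - mu_i) / sigma_i`, forcing every probeset to mean 0 and
#' standard deviation 1 across tissues. Population (divide-by-N) standard
#' deviations are used in both steps. Constant columns/rows (zero standard
#' deviation) are dropped with a warning. Probeset averaging per gene and
#' duplicate-tissue averaging are separate, later steps (see
#' [collapse_probesets()] and [average_duplicate_tissues()]).
#'
#' @param mat numeric matrix, probesets x tissues, no missing values.
#' @return object of class `expression_norm`: list with matrices `s`
#'   (input after drops), `t`, `n`, and character vectors `dropped_tissues`,
#'   `dropped_rows`.
#' @export
normalize_two_step <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (anyNA(mat)) stop("expression matrix must not contain missing values")
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need at least 2 probesets and 2 tissues")
  sd_j <- apply(mat, 2, pop_sd)
  dropped_tissues <- colnames(mat)[sd_j == 0]
  if (length(dropped_tissues)) {
    warning("dropping constant tissue column(s): ",
            paste(dropped_tissues, collapse = ", "))
    mat <- mat[, sd_j > 0, drop = FALSE]
    sd_j <- sd_j[sd_j > 0]
  }
  t_mat <- sweep(sweep(mat, 2, colMeans(mat)), 2, sd_j, "/")
  sd_i <- apply(t_mat, 1, pop_sd)
  dropped_rows <- rownames(t_mat)[sd_i == 0]
  if (length(dropped_rows)) {
    warning("dropping constant probeset row(s): ",
            paste(dropped_rows, collapse = ", "))
    t_mat <- t_mat[sd_i > 0, , drop = FALSE]
    mat <- mat[sd_i > 0, , drop = FALSE]
    sd_i <- sd_i[sd_i > 0]
  }
  n_mat <- sweep(sweep(t_mat, 1, rowMeans(t_mat)), 1, sd_i, "/")
  structure(list(s = mat, t = t_mat, n = n_mat,
                 dropped_tissues = dropped_tissues, dropped_rows = dropped_rows),
            class = "expression_norm")
}

#' @export
print.expression_norm <- function(x, ...) {
  cat(sprintf("expression_norm: %d probesets x %d tissues (%d tissue(s), %d row(s) dropped)\n",
              nrow(x$n), ncol(x$n), length(x$dropped_tissues), length(x$dropped_rows)))
  invisible(x)
}

#' Average normalized probesets that map to the same gene
#'
#' @param n_mat normalized matrix (`n` element of [normalize_two_step()]).
#' @param map data frame from [map_probes_to_genes()].
#' @return gene x tissue matrix (genes with no retained probeset absent).
#' @export
collapse_probesets <- function(n_mat, map) {
  map <- map[map$probeset_id %in% rownames(n_mat), , drop = FALSE]
  if (nrow(map) == 0L) stop("no mapped probesets present in the matrix")
  rows <- n_mat[map$probeset_id, , drop = FALSE]
  out <- rowsum(rows, group = map$gene_id) / as.vector(table(map$gene_id)[sort(unique(map$gene_id))])
  out[sort(unique(map$gene_id)), , drop = FALSE]
}

#' Average duplicate tissue columns
#'
#' Columns sharing a tissue name (duplicate samples of the same tissue) are
#' averaged into one column.
#'
#' @param mat matrix with tissue names as column names.
#' @return matrix with unique, sorted tissue columns.
#' @export
average_duplicate_tissues <- function(mat) {
  tiss <- colnames(mat)
  if (is.null(tiss)) stop("matrix must have tissue column names")
  t(rowsum(t(mat), group = tiss) / as.vector(table(tiss)[sort(unique(tiss))]))
}

#' Expression similarity between two genes across tissues
#'
#' Pearson correlation of the normalized expression profiles restricted to
#' `tissues` (default: all shared columns). Euclidean distance is available
#' as an alternative measure. Zero-variance profiles give `NA`.
#'
#' @param expr gene x tissue matrix of normalized values.
#' @param gene_p,gene_q gene ids (rows of `expr`).
#' @param tissues tissue names to use (>= 3).
#' @param method `"pearson"` (similarity in `[-1, 1]`) or `"euclidean"`
#'   (a distance, >= 0).
#' @return numeric scalar (or `NA` if undefined).
#' @export
expression_similarity <- function(expr, gene_p, gene_q, tissues = colnames(expr),
                                  method = c("pearson", "euclidean")) {
  method <- match.arg(method)
  if (!(gene_p %in% rownames(expr)) || !(gene_q %in% rownames(expr))) return(NA_real_)
  tissues <- intersect(tissues, colnames(expr))
  if (length(tissues) < 3) stop("need at least 3 tissues")
  x <- expr[gene_p, tissues]
  y <- expr[gene_q, tissues]
  if (method == "euclidean") return(sqrt(sum((x - y)^2)))
  if (pop_sd(x) == 0 || pop_sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
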