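# Assembling the per-pair similarity table and the headline analyses:
# binned similarity-versus-divergence curves, pooled rank-sum class
# comparisons, rank-correlation trend tests, and the intra- versus
# interchromosomal split of within-species paralogs.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Assemble the per-pair similarity table
#'
#' Joins classified homolog pairs with sequence identity/divergence,
#' per-namespace functional similarity, and expression correlation. Each
#' measure is present only where both members qualify for it (`NA`
#' otherwise). `same_chromosome` is defined for within-species pairs only.
#'
#' @param pairs classified pair table (`gene_a`, `gene_b`, `class`,
#'   `family_id`), e.g. from [classify_forest()].
#' @param seq_results data frame keyed by `gene_a`, `gene_b` with
#'   `identity` and optionally `dN`, `dS`, `dn_ds` (see [align_pairs()]).
#' @param fs_bp,fs_mf optional data frames keyed by `gene_a`, `gene_b` with
#'   an `fs` column for the two namespaces.
#' @param expr_cor optional data frame keyed by `gene_a`, `gene_b` with a
#'   column `expr_cor`.
#' @param gene_table data frame with `gene_id`, `species`, `chromosome`.
#' @return data frame with one row per classified pair: the pair columns
#'   plus `identity`, `dN`, `dS`, `dn_ds`, `fs_BP`, `fs_MF`, `expr_cor`,
#'   `same_chromosome`.
#' @export
assemble_pair_table <- function(pairs, seq_results, fs_bp = NULL, fs_mf = NULL,
                                expr_cor = NULL, gene_table = NULL) {
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  if (anyDuplicated(key)) {
    stop("duplicate pair rows in classified pairs: ",
         paste(utils::head(pairs$gene_a[duplicated(key)], 3), collapse = ", "))
  }
  out <- pairs
  pull <- function(tab, col, default = NA_real_) {
    if (is.null(tab) || !(col %in% names(tab))) return(rep(default, nrow(out)))
    k <- pair_key(tab$gene_a, tab$gene_b)
    if (anyDuplicated(k)) stop("duplicate pair rows in '", col, "' input")
    as.numeric(tab[[col]][match(key, k)])
  }
  out$identity <- pull(seq_results, "identity")
  out$dN <- pull(seq_results, "dN")
  out$dS <- pull(seq_results, "dS")
  out$dn_ds <- pull(seq_results, "dn_ds")
  out$fs_BP <- pull(fs_bp, "fs")
  out$fs_MF <- pull(fs_mf, "fs")
  out$expr_cor <- pull(expr_cor, "expr_cor")
  same_chrom <- rep(NA, nrow(out))
  if (!is.null(gene_table)) {
    sp <- stats::setNames(gene_table$species, gene_table$gene_id)
    ch <- stats::setNames(gene_table$chromosome, gene_table$gene_id)
    within <- sp[out$gene_a] == sp[out$gene_b]
    same_chrom[within] <- (ch[out$gene_a] == ch[out$gene_b])[within]
  }
  out$same_chromosome <- same_chrom
  out
}

#' Default identity bin edges
#'
#' 0.50 to 1.00 in steps of 0.05. Pairs below 0.50 identity are excluded
#' from ortholog-versus-paralog comparisons (too few low-identity one-to-one
#' orthologs exist to support them) but paralog-only curves may extend lower.
#' @param lo,hi,by numeric bin range and width.
#' @return numeric vector of edges.
#' @export
identity_bins <- function(lo = 0.5, hi = 1.0, by = 0.05) seq(lo, hi, by = by)

bin_assign <- function(x, edges) {
  # half-open [lo, hi) bins, last bin closed
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b[b < 1L | b >= length(edges) | x < edges[1] | x > edges[length(edges)]] <- NA_integer_
  b
}

#' Binned mean and standard error of a similarity measure
#'
#' Bins records on a divergence axis into half-open `[lo, hi)` bins (last
#' bin closed) and reports per-bin n, mean and standard error
#' (sample sd / sqrt(n); `SE = 0` and flagged when `n = 1`).
#'
#' @param records pair table from [assemble_pair_table()].
#' @param x_variable,y_variable column names (e.g. `"identity"`, `"fs_BP"`).
#' @param classes optional character vector of classes to keep.
#' @param edges bin edges (default [identity_bins()]).
#' @return object of class `binned_curve`: data frame with `bin_lo`,
#'   `bin_hi`, `mid`, `n`, `mean`, `se`, `se_flagged`. Empty selections give
#'   a zero-row curve with a warning.
#' @export
bin_curve <- function(records, x_variable = "identity", y_variable = "fs_BP",
                      classes = NULL, edges = identity_bins()) {
  stopifnot(x_variable %in% names(records), y_variable %in% names(records))
  if (!is.null(classes)) records <- records[records$class %in% classes, , drop = FALSE]
  x <- records[[x_variable]]
  y <- records[[y_variable]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) {
    warning("no records selected for the curve")
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0), mid = numeric(0),
                      n = integer(0), mean = numeric(0), se = numeric(0),
                      se_flagged = logical(0))
    class(out) <- c("binned_curve", "data.frame")
    return(out)
  }
  b <- bin_assign(x, edges)
  rows <- lapply(seq_len(length(edges) - 1L), function(i) {
    yi <- y[!is.na(b) & b == i]
    if (length(yi) == 0L) return(NULL)
    data.frame(bin_lo = edges[i], bin_hi = edges[i + 1L],
               mid = (edges[i] + edges[i + 1L]) / 2,
               n = length(yi), mean = mean(yi),
               se = if (length(yi) > 1L) stats::sd(yi) / sqrt(length(yi)) else 0,
               se_flagged = length(yi) == 1L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("binned_curve", "data.frame")
  out
}

rank_sum_exact_p <- function(ya, yb) {
  # exact conditional two-sided p-value of the rank-sum statistic with
  # midranks, by complete enumeration of group assignments
  r <- rank(c(ya, yb))
  na <- length(ya); n <- length(r)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  idx <- utils::combn(n, na)
  w_all <- colSums(matrix(r[idx], nrow = na))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Rank-sum comparison of two homolog classes
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of a similarity measure
#' between two classes, pooled over all pairs at or above an identity
#' threshold (pooling rather than bin-by-bin testing). Small samples (both
#' groups <= 8) are tested by exact enumeration of the conditional
#' permutation distribution (valid with ties); larger samples use the
#' tie-corrected normal approximation. `direction` is the sign of
#' `mean(class_a) - mean(class_b)`.
#'
#' @param records pair table.
#' @param class_a,class_b class labels (each may be a vector of labels).
#' @param y_variable similarity column.
#' @param identity_threshold keep pairs with `identity >= threshold`
#'   (`-Inf` to disable).
#' @return list with `p_value`, `direction`, `statistic` (rank sum of
#'   `class_a`), `n_a`, `n_b`, `method`.
#' @export
compare_classes <- function(records, class_a, class_b, y_variable = "fs_BP",
                            identity_threshold = 0.7) {
  sel <- records[!is.na(records[[y_variable]]) &
                   !is.na(records$identity) &
                   records$identity >= identity_threshold, , drop = FALSE]
  ya <- sel[[y_variable]][sel$class %in% class_a]
  yb <- sel[[y_variable]][sel$class %in% class_b]
  if (length(ya) == 0L) stop("no records for class ", paste(class_a, collapse = "/"))
  if (length(yb) == 0L) stop("no records for class ", paste(class_b, collapse = "/"))
  if (length(ya) <= 8 && length(yb) <= 8) {
    p <- rank_sum_exact_p(ya, yb)
    method <- "exact enumeration"
  } else {
    p <- stats::wilcox.test(ya, yb, exact = FALSE, correct = FALSE)$p.value
    method <- "tie-corrected normal approximation"
  }
  list(p_value = p,
       direction = sign(mean(ya) - mean(yb)),
       statistic = sum(rank(c(ya, yb))[seq_along(ya)]),
       n_a = length(ya), n_b = length(yb), method = method)
}

#' Bin-matched (stratified) rank-sum comparison of two classes
#'
#' Van Elteren-style combination of per-bin rank-sum statistics over the
#' divergence bins in which both classes are represented, removing the
#' confounding of class with divergence when the two classes occupy
#' different parts of the axis.
#'
#' @inheritParams compare_classes
#' @param x_variable binning axis.
#' @param edges bin edges.
#' @param min_per_class minimum pairs per class for a bin to enter.
#' @return list with `p_value`, `z`, `direction` (sign of the pooled
#'   bin-weighted mean difference), `n_bins`, `n_a`, `n_b`, and per-bin
#'   means `bin_means` (data frame).
#' @export
compare_classes_matched <- function(records, class_a, class_b,
                                    y_variable = "fs_BP",
                                    x_variable = "identity",
                                    edges = identity_bins(),
                                    min_per_class = 5L) {
  sel <- records[!is.na(records[[y_variable]]) & !is.na(records[[x_variable]]) &
                   (records$class %in% c(class_a, class_b)), , drop = FALSE]
  sel$grp <- ifelse(sel$class %in% class_a, "a", "b")
  sel$bin <- bin_assign(sel[[x_variable]], edges)
  sel <- sel[!is.na(sel$bin), , drop = FALSE]
  num <- den <- 0
  n_bins <- 0L; n_a <- 0L; n_b <- 0L
  dmeans <- numeric(0)
  rows <- list()
  for (b in sort(unique(sel$bin))) {
    sb <- sel[sel$bin == b, , drop = FALSE]
    na <- sum(sb$grp == "a"); nb <- sum(sb$grp == "b")
    if (na < min_per_class || nb < min_per_class) next
    r <- rank(sb[[y_variable]])
    n <- na + nb
    w <- sum(r[sb$grp == "a"])
    mu <- na * (n + 1) / 2
    # tie-corrected variance of the rank sum
    ties <- table(r)
    v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) next
    # van Elteren weights: 1 / (n + 1)
    num <- num + (w - mu) / (n + 1)
    den <- den + v / (n + 1)^2
    n_bins <- n_bins + 1L; n_a <- n_a + na; n_b <- n_b + nb
    ma <- mean(sb[[y_variable]][sb$grp == "a"])
    mb <- mean(sb[[y_variable]][sb$grp == "b"])
    dmeans <- c(dmeans, ma - mb)
    rows[[length(rows) + 1L]] <- data.frame(
      bin_lo = edges[b], bin_hi = edges[b + 1L], n_a = na, n_b = nb,
      mean_a = ma, mean_b = mb)
  }
  if (n_bins == 0L) stop("no bins contain both classes at the required size")
  z <- num / sqrt(den)
  list(p_value = 2 * stats::pnorm(-abs(z)), z = z,
       direction = sign(mean(dmeans)),
       n_bins = n_bins, n_a = n_a, n_b = n_b,
       bin_means = do.call(rbind, rows))
}

#' Rank correlation between divergence and similarity
#'
#' Spearman rank correlation over unbinned records, with midranks for ties.
#' The p-value is exact (via the null distribution of the rank statistic)
#' when the sample is small and tie-free, otherwise asymptotic.
#'
#' @param records pair table.
#' @param classes optional class filter.
#' @param x_variable,y_variable column names.
#' @return list with `rho`, `p_value`, `n`. `rho` is `NA` (flagged via
#'   `undefined = TRUE`) when either variable is constant.
#' @export
trend_correlation <- function(records, classes = NULL, x_variable = "identity",
                              y_variable = "fs_BP") {
  if (!is.null(classes)) records <- records[records$class %in% classes, , drop = FALSE]
  x <- records[[x_variable]]
  y <- records[[y_variable]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x), undefined = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       undefined = FALSE)
}

#' Same- versus different-chromosome paralog curves
#'
#' Restricts to within-species paralogs (inparalogs and within-species
#' outparalogs) with defined chromosome labels and returns one binned curve
#' for pairs on the same chromosome and one for pairs on different
#' chromosomes.
#'
#' @param records pair table.
#' @param y_variable similarity column.
#' @param edges bin edges.
#' @return list with `same`, `different` (binned curves) and `n_excluded`
#'   (within-species pairs lacking a chromosome label).
#' @export
chromosome_split_curves <- function(records, y_variable = "fs_BP",
                                    edges = identity_bins()) {
  within <- records[records$class %in% c("inparalog", "within_species_outparalog"), ,
                    drop = FALSE]
  n_excluded <- sum(is.na(within$same_chromosome))
  within <- within[!is.na(within$same_chromosome), , drop = FALSE]
  list(
    same = bin_curve(within[within$same_chromosome, , drop = FALSE],
                     "identity", y_variable, edges = edges),
    different = bin_curve(within[!within$same_chromosome, , drop = FALSE],
                          "identity", y_variable, edges = edges),
    n_excluded = n_excluded
  )
}
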