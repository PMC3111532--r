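# Family-based best-ortholog versus best-paralog analysis.
#
# Per family, one annotated target protein with at least one annotated
# ortholog and at least one annotated paralog is drawn uniformly at random;
# the comparison ortholog is the annotated ortholog of highest sequence
# identity to the target; the family contributes a single count to a 2x2
# table (rows: does any annotated paralog beat that ortholog's identity;
# columns: does the best paralog's functional similarity beat the
# ortholog's). The draw is repeated (100 times by default) and per-cell
# means and standard errors are reported. One-to-many and many-to-many
# orthologs are admitted; "paralog" means any paralog class.

ortholog_class_set <- function() c("ortholog_1to1", "ortholog_1toMany")
paralog_class_set <- function() {
  c("inparalog", "within_species_outparalog", "between_species_outparalog")
}

family_partner_table <- function(family_pairs, fs_col) {
  ok <- !is.na(family_pairs$identity) & !is.na(family_pairs[[fs_col]])
  fp <- family_pairs[ok, , drop = FALSE]
  if (nrow(fp) == 0L) return(NULL)
  # long format: one row per (protein, partner)
  rbind(
    data.frame(protein = fp$gene_a, partner = fp$gene_b, class = fp$class,
               identity = fp$identity, fs = fp[[fs_col]], stringsAsFactors = FALSE),
    data.frame(protein = fp$gene_b, partner = fp$gene_a, class = fp$class,
               identity = fp$identity, fs = fp[[fs_col]], stringsAsFactors = FALSE)
  )
}

#' Eligible target proteins of one family
#'
#' Proteins that have, within the family and in the chosen namespace, at
#' least one annotated ortholog (any orthology cardinality) and at least one
#' annotated paralog of any type, both with measured identity and functional
#' similarity. Pairs with missing measures do not qualify as partners.
#'
#' @param family_pairs the rows of a pair table belonging to one family.
#' @param fs_col functional-similarity column (`"fs_BP"` or `"fs_MF"`).
#' @return character vector of protein ids (possibly empty).
#' @export
eligible_targets <- function(family_pairs, fs_col = "fs_BP") {
  long <- family_partner_table(family_pairs, fs_col)
  if (is.null(long)) return(character(0))
  has_orth <- tapply(long$class %in% ortholog_class_set(), long$protein, any)
  has_par <- tapply(long$class %in% paralog_class_set(), long$protein, any)
  sort(names(has_orth)[has_orth & has_par[names(has_orth)]])
}

#' One replicate of the family-based analysis
#'
#' Draws one eligible target per family (uniformly, using the current RNG
#' state) and tallies the 2x2 counts. Identity ties for the comparison
#' ortholog are broken toward the lexicographically smallest gene id;
#' functional-similarity ties credit the ortholog.
#'
#' @param pair_table assembled pair table ([assemble_pair_table()]).
#' @param fs_col functional-similarity column.
#' @return 2x2 integer matrix; rows `paralog_higher_identity`,
#'   `ortholog_higher_identity`; columns `paralog_higher_fs`,
#'   `ortholog_higher_fs`.
#' @export
run_family_replicate <- function(pair_table, fs_col = "fs_BP") {
  counts <- matrix(0L, 2, 2,
                   dimnames = list(c("paralog_higher_identity", "ortholog_higher_identity"),
                                   c("paralog_higher_fs", "ortholog_higher_fs")))
  for (fam in unique(pair_table$family_id)) {
    fp <- pair_table[pair_table$family_id == fam, , drop = FALSE]
    targets <- eligible_targets(fp, fs_col)
    if (length(targets) == 0L) next
    target <- targets[sample.int(length(targets), 1L)]
    long <- family_partner_table(fp, fs_col)
    mine <- long[long$protein == target, , drop = FALSE]
    orth <- mine[mine$class %in% ortholog_class_set(), , drop = FALSE]
    par <- mine[mine$class %in% paralog_class_set(), , drop = FALSE]
    # comparison ortholog: highest identity, ties -> smallest gene id
    orth <- orth[order(-orth$identity, orth$partner), , drop = FALSE]
    o <- orth[1L, ]
    row <- if (any(par$identity > o$identity)) 1L else 2L
    col <- if (max(par$fs) > o$fs) 1L else 2L
    counts[row, col] <- counts[row, col] + 1L
  }
  counts
}

#' Repeated family-based analysis
#'
#' Repeats [run_family_replicate()] `n_reps` times with fresh random target
#' draws (per-replicate RNG substreams derived deterministically from
#' `seed`) and summarizes per-cell means and standard errors across
#' replicates, plus the row-conditional percentages (e.g. "in x% of families
#' where an ortholog had the highest sequence identity, the ortholog also
#' had the highest functional similarity").
#'
#' @param pair_table assembled pair table.
#' @param fs_col functional-similarity column.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed for the target draws.
#' @return object of class `family_counts`: list with `mean`, `se` (2x2
#'   matrices), `percent` (row-conditional percentages, mean and se), and
#'   `replicates` (n_reps x 4 matrix of raw counts).
#' @export
run_family_analysis <- function(pair_table, fs_col = "fs_BP", n_reps = 100,
                                seed = 1) {
  stopifnot(n_reps >= 1)
  rep_seeds <- withr_seed_draw(seed, n_reps)
  reps <- matrix(NA_real_, n_reps, 4)
  colnames(reps) <- c("par_id_par_fs", "par_id_orth_fs", "orth_id_par_fs", "orth_id_orth_fs")
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    cc <- run_family_replicate(pair_table, fs_col)
    reps[r, ] <- c(cc[1, 1], cc[1, 2], cc[2, 1], cc[2, 2])
  }
  mean_mat <- matrix(colMeans(reps), 2, 2, byrow = TRUE,
                     dimnames = list(c("paralog_higher_identity", "ortholog_higher_identity"),
                                     c("paralog_higher_fs", "ortholog_higher_fs")))
  se_vec <- apply(reps, 2, function(v) stats::sd(v) / sqrt(n_reps))
  se_mat <- matrix(se_vec, 2, 2, byrow = TRUE, dimnames = dimnames(mean_mat))
  pct <- function(win, total) 100 * win / total
  pr <- cbind(
    par_row_par_fs = pct(reps[, "par_id_par_fs"], reps[, "par_id_par_fs"] + reps[, "par_id_orth_fs"]),
    orth_row_orth_fs = pct(reps[, "orth_id_orth_fs"], reps[, "orth_id_par_fs"] + reps[, "orth_id_orth_fs"])
  )
  percent <- data.frame(
    quantity = c("paralog_best_sequence_and_function",
                 "ortholog_best_sequence_and_function"),
    mean = colMeans(pr, na.rm = TRUE),
    se = apply(pr, 2, function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  )
  structure(list(mean = mean_mat, se = se_mat, percent = percent,
                 replicates = reps, n_reps = n_reps, seed = seed),
            class = "family_counts")
}

# deterministic per-replicate seeds from a top-level seed (kept < 2^31)
withr_seed_draw <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' @export
print.family_counts <- function(x, ...) {
  cat(sprintf("family-based analysis over %d replicates (seed %s)\n", x$n_reps, x$seed))
  m <- matrix(sprintf("%.1f +/- %.1f", x$mean, x$se), 2, 2, dimnames = dimnames(x$mean))
  print(m, quote = FALSE)
  for (i in seq_len(nrow(x$percent))) {
    cat(sprintf("%s: %.1f +/- %.1f%%\n", x$percent$quantity[i],
                x$percent$mean[i], x$percent$se[i]))
  }
  invisible(x)
}
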