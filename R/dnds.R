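# Synonymous / nonsynonymous divergence by the Nei-Gojobori (1986) counting
# method with Jukes-Cantor correction.
#
# Synonymous site counts: at each codon position, the fraction of the three
# possible nucleotide changes that leave the amino acid unchanged; a change
# that creates a stop codon counts as nonsynonymous. Differences between two
# codons are averaged over all minimal mutational pathways (orders of the
# differing positions), excluding pathways that pass through a stop codon
# (all pathways are used if every one is blocked). Proportions are corrected
# with the Jukes-Cantor formula; dS is flagged unreliable once pS >= 0.75
# where the correction diverges.

.dnds_env <- new.env(parent = emptyenv())

codon_universe <- function() {
  nts <- c("T", "C", "A", "G")
  as.vector(outer(outer(nts, nts, paste0), nts, paste0))
}

codon_tables <- function() {
  if (!is.null(.dnds_env$tables)) return(.dnds_env$tables)
  gc <- Biostrings::GENETIC_CODE
  codons <- codon_universe()
  aa <- gc[codons]
  nts <- c("T", "C", "A", "G")
  # synonymous sites per codon
  syn_sites <- stats::setNames(numeric(64), codons)
  for (c0 in codons) {
    if (aa[c0] == "*") { syn_sites[c0] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(c0, pos, pos))) {
        c1 <- c0
        substr(c1, pos, pos) <- nt
        if (aa[c1] != "*" && aa[c1] == aa[c0]) s <- s + 1 / 3
      }
    }
    syn_sites[c0] <- s
  }
  # pathway-averaged differences for every codon pair
  sd_mat <- nd_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                           c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (ca in codons) {
    if (aa[ca] == "*") next
    for (cb in codons) {
      if (aa[cb] == "*") next
      diffpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
      nd <- length(diffpos)
      if (nd == 0L) { sd_mat[ca, cb] <- 0; nd_mat[ca, cb] <- 0; next }
      paths <- perms[[as.character(nd)]]
      path_s <- path_n <- numeric(0)
      for (ord in paths) {
        cur <- ca
        s <- n <- 0
        ok <- TRUE
        for (step in diffpos[ord]) {
          nxt <- cur
          substr(nxt, step, step) <- substr(cb, step, step)
          if (aa[nxt] == "*") { ok <- FALSE; break }
          if (aa[nxt] == aa[cur]) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        if (ok) { path_s <- c(path_s, s); path_n <- c(path_n, n) }
      }
      if (length(path_s) == 0L) {
        # all pathways blocked by stops: fall back to averaging over all,
        # counting the blocked step as nonsynonymous
        for (ord in paths) {
          cur <- ca
          s <- n <- 0
          for (step in diffpos[ord]) {
            nxt <- cur
            substr(nxt, step, step) <- substr(cb, step, step)
            if (aa[nxt] == "*" || aa[nxt] != aa[cur]) n <- n + 1 else s <- s + 1
            cur <- nxt
          }
          path_s <- c(path_s, s); path_n <- c(path_n, n)
        }
      }
      sd_mat[ca, cb] <- mean(path_s)
      nd_mat[ca, cb] <- mean(path_n)
    }
  }
  .dnds_env$tables <- list(codons = codons, aa = aa, syn_sites = syn_sites,
                           sd = sd_mat, nd = nd_mat)
  .dnds_env$tables
}

split_codons <- function(cds, arg) {
  cds <- toupper(gsub("U", "T", cds))
  if (nchar(cds) %% 3 != 0) stop(arg, " length is not a multiple of 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori divergence between two coding sequences
#'
#' Counts synonymous and nonsynonymous sites and differences over the codon
#' alignment implied by a protein alignment (codons aligned to a gap are
#' excluded), averages differences over minimal mutational pathways, and
#' applies the Jukes-Cantor correction to each proportion. `dS` (and hence
#' `dN/dS`) is set to `NA` and flagged once the synonymous proportion
#' reaches 0.75, where the correction is undefined; `dN/dS` is likewise
#' `NA` when `dS = 0`.
#'
#' @param cds_a,cds_b in-frame coding sequences, each 3x the length of the
#'   corresponding protein (a trailing stop codon is tolerated and trimmed).
#' @param protein_alignment optional `alignment_result` from
#'   [global_align()] of the two translated proteins; if omitted the
#'   sequences must be the same length and are compared codon by codon.
#' @return list with `dN`, `dS`, `dn_ds`, site counts `S`, `N`, difference
#'   counts `Sd`, `Nd`, and logical `ds_unreliable`.
#' @export
estimate_divergence <- function(cds_a, cds_b, protein_alignment = NULL) {
  tab <- codon_tables()
  ca <- split_codons(cds_a, "cds_a")
  cb <- split_codons(cds_b, "cds_b")
  # trim a trailing stop codon
  if (length(ca) && !is.na(tab$aa[ca[length(ca)]]) && tab$aa[ca[length(ca)]] == "*") ca <- ca[-length(ca)]
  if (length(cb) && !is.na(tab$aa[cb[length(cb)]]) && tab$aa[cb[length(cb)]] == "*") cb <- cb[-length(cb)]
  if (any(tab$aa[ca] == "*", na.rm = TRUE)) stop("internal stop codon in cds_a")
  if (any(tab$aa[cb] == "*", na.rm = TRUE)) stop("internal stop codon in cds_b")
  if (is.null(protein_alignment)) {
    if (length(ca) != length(cb)) {
      stop("without a protein alignment the coding sequences must have equal length")
    }
    ia <- seq_along(ca); ib <- seq_along(cb)
  } else {
    stopifnot(inherits(protein_alignment, "alignment_result"))
    aa_cols <- strsplit(protein_alignment$aligned_a, "")[[1]]
    bb_cols <- strsplit(protein_alignment$aligned_b, "")[[1]]
    if (sum(aa_cols != "-") != length(ca)) stop("cds_a does not match the aligned protein length")
    if (sum(bb_cols != "-") != length(cb)) stop("cds_b does not match the aligned protein length")
    ia <- ib <- integer(0)
    pa <- pb <- 0L
    for (col in seq_along(aa_cols)) {
      ga <- aa_cols[col] != "-"; gb <- bb_cols[col] != "-"
      if (ga) pa <- pa + 1L
      if (gb) pb <- pb + 1L
      if (ga && gb) { ia <- c(ia, pa); ib <- c(ib, pb) }
    }
  }
  ca <- ca[ia]; cb <- cb[ib]
  keep <- grepl("^[TCAG]{3}$", ca) & grepl("^[TCAG]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("no comparable codons")
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tab$sd[cbind(ca, cb)])
  Nd <- sum(tab$nd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  unreliable <- pS >= 0.75
  dn_ds <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(dN = dN, dS = dS, dn_ds = dn_ds, S = S, N = N, Sd = Sd, Nd = Nd,
       ds_unreliable = unreliable)
}
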