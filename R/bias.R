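# Robustness filters: each is a pure contraction of annotations or pairs
# that re-feeds the standard curve pipeline, used to check that the
# qualitative ortholog/paralog patterns are not artifacts of annotation
# practice.

filter_report <- function(name, records_before, records_after,
                          pairs_before = NA_integer_, pairs_after = NA_integer_) {
  structure(list(filter = name,
                 records_before = records_before, records_after = records_after,
                 pairs_before = pairs_before, pairs_after = pairs_after),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': records %d -> %d", x$filter,
              x$records_before, x$records_after))
  if (!is.na(x$pairs_before)) {
    cat(sprintf(", pairs %d -> %d", x$pairs_before, x$pairs_after))
  }
  cat("\n")
  invisible(x)
}

#' Keep only terms annotated in both species
#'
#' Removes from every propagated set any term that is not present in the
#' propagated annotation of at least one protein of each species; proteins
#' whose set becomes empty are dropped. This controls for organism-specific
#' annotation (functions studied only in one species).
#'
#' @param sets named list protein -> propagated term set.
#' @param species named character vector protein -> species.
#' @return list with `sets` (filtered) and `report` (a `filter_report`).
#' @export
filter_shared_species_terms <- function(sets, species) {
  sp <- unique(species[names(sets)])
  if (length(sp) < 2) stop("need proteins from two species")
  per_species <- lapply(sp, function(s) {
    unique(unlist(sets[names(sets)[species[names(sets)] == s]], use.names = FALSE))
  })
  shared <- Reduce(intersect, per_species)
  before <- sum(lengths(sets))
  out <- lapply(sets, function(tt) tt[tt %in% shared])
  out <- out[lengths(out) > 0L]
  list(sets = out,
       report = filter_report("shared_species_terms", before, sum(lengths(out))))
}

#' Truncate annotation depth within each family
#'
#' For each family, computes every protein's maximal term depth, takes the
#' minimum of those maxima (d*), and removes from every protein in the
#' family all terms deeper than d*. Proteins annotated with very specific
#' terms are thereby generalized to the depth of the most generally
#' annotated family member. Since every propagated set contains a term of
#' depth 1 (a child of the root), truncation never empties a set.
#'
#' @param sets named list protein -> propagated term set.
#' @param families named character vector protein -> family id.
#' @param dag the `ontology_dag` (for term depths).
#' @param method depth definition, see [term_depth()].
#' @return list with `sets` and `report`.
#' @export
truncate_family_depth <- function(sets, families, dag,
                                  method = c("shortest", "longest")) {
  method <- match.arg(method)
  depth <- term_depth(dag, method = method)
  before <- sum(lengths(sets))
  prots <- names(sets)
  fam <- families[prots]
  out <- sets
  for (f in unique(fam[!is.na(fam)])) {
    members <- prots[!is.na(fam) & fam == f]
    if (length(members) < 2) next
    maxd <- vapply(members, function(p) max(depth[sets[[p]]]), numeric(1))
    dstar <- min(maxd)
    for (p in members) {
      out[[p]] <- sets[[p]][depth[sets[[p]]] <= dstar]
    }
  }
  list(sets = out,
       report = filter_report("family_depth_truncation", before, sum(lengths(out))))
}

parse_pubmed_ids <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) unique(trimws(v[nzchar(trimws(v))])))
}

#' Per-pair publication filter on direct annotations
#'
#' Controls for the tendency of annotations reported in the same publication
#' to agree. For a homologous pair, a direct annotation is retained iff it
#' can be certified by a publication id choice that does not collide with
#' the partner's: two annotations conflict only when both can be supported
#' solely by one and the same publication id (if different ids can be
#' assigned to the two sides, both are kept). `mode = "same_only"` inverts
#' the filter and keeps only annotations sharing at least one publication id
#' with some annotation of the partner.
#'
#' @param records_p,records_q data frames of direct annotation records for
#'   the two proteins, with columns `term_id` and `pubmed_ids`
#'   (semicolon-separated).
#' @param mode `"separate"` (drop unavoidable same-publication support) or
#'   `"same_only"` (keep only same-publication support).
#' @return list with filtered `records_p`, `records_q`.
#' @export
pair_publication_filter <- function(records_p, records_q,
                                    mode = c("separate", "same_only")) {
  mode <- match.arg(mode)
  pp <- parse_pubmed_ids(records_p$pubmed_ids)
  pq <- parse_pubmed_ids(records_q$pubmed_ids)
  if (mode == "same_only") {
    keep_p <- vapply(pp, function(a) any(vapply(pq, function(b) length(intersect(a, b)) > 0, logical(1))), logical(1))
    keep_q <- vapply(pq, function(b) any(vapply(pp, function(a) length(intersect(a, b)) > 0, logical(1))), logical(1))
  } else {
    # an annotation pair is irreconcilable iff both sides are supported by
    # exactly the same single publication; otherwise distinct ids exist
    conflict <- function(a, b) length(unique(c(a, b))) < 2
    keep_p <- vapply(pp, function(a) !any(vapply(pq, function(b) conflict(a, b), logical(1))), logical(1))
    keep_q <- vapply(pq, function(b) !any(vapply(pp, function(a) conflict(a, b), logical(1))), logical(1))
  }
  list(records_p = records_p[keep_p, , drop = FALSE],
       records_q = records_q[keep_q, , drop = FALSE])
}

#' Evidence-code restrictions
#'
#' `drop_TAS` removes all annotations with the traceable-author-statement
#' code before propagation (proteins supported only by TAS drop out of the
#' analysis). `same_code` is a pair-level filter: see
#' [pair_same_evidence_filter()].
#'
#' @param records direct annotation records with an `evidence_code` column.
#' @return list with `records` (filtered) and `report`.
#' @export
restrict_evidence <- function(records) {
  bad <- setdiff(unique(records$evidence_code), go_evidence_codes())
  if (length(bad)) stop("unknown evidence code(s): ", paste(bad, collapse = ", "))
  keep <- records$evidence_code != "TAS"
  list(records = records[keep, , drop = FALSE],
       report = filter_report("drop_TAS", nrow(records), sum(keep)))
}

#' Per-pair same-evidence-code filter
#'
#' Keeps, for a homologous pair, only annotations whose evidence code is
#' used by both proteins (code-level matching before propagation). With
#' `per_protein = TRUE` the pair is kept unchanged only if the two proteins'
#' full evidence-code sets are identical, and both sides are emptied
#' otherwise.
#'
#' @param records_p,records_q direct annotation records of the two proteins.
#' @param per_protein require identical code sets instead of per-annotation
#'   code matching.
#' @return list with filtered `records_p`, `records_q`.
#' @export
pair_same_evidence_filter <- function(records_p, records_q, per_protein = FALSE) {
  bad <- setdiff(unique(c(records_p$evidence_code, records_q$evidence_code)),
                 go_evidence_codes())
  if (length(bad)) stop("unknown evidence code(s): ", paste(bad, collapse = ", "))
  cp <- unique(records_p$evidence_code)
  cq <- unique(records_q$evidence_code)
  if (per_protein) {
    if (setequal(cp, cq)) {
      return(list(records_p = records_p, records_q = records_q))
    }
    return(list(records_p = records_p[0, , drop = FALSE],
                records_q = records_q[0, , drop = FALSE]))
  }
  shared <- intersect(cp, cq)
  list(records_p = records_p[records_p$evidence_code %in% shared, , drop = FALSE],
       records_q = records_q[records_q$evidence_code %in% shared, , drop = FALSE])
}

#' Pair functional similarity under a per-pair annotation filter
#'
#' Applies a per-pair filter to the two proteins' direct annotations,
#' re-propagates the surviving records, and computes the Maryland bridge
#' similarity. Pairs where either side ends up unannotated get `NA`.
#'
#' @param pairs pair table (`gene_a`, `gene_b`).
#' @param records direct annotation records (all proteins, one namespace).
#' @param dag the `ontology_dag`.
#' @param pair_filter function of two record frames returning a list with
#'   `records_p`, `records_q` (e.g. [pair_publication_filter()] or
#'   [pair_same_evidence_filter()], possibly with arguments fixed).
#' @return `pairs` with an `fs` column.
#' @export
pair_fs_filtered <- function(pairs, records, dag, pair_filter) {
  by_prot <- split(records, records$protein_id)
  fs <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    rp <- by_prot[[pairs$gene_a[k]]]
    rq <- by_prot[[pairs$gene_b[k]]]
    if (is.null(rp) || is.null(rq)) next
    flt <- pair_filter(rp, rq)
    if (nrow(flt$records_p) == 0L || nrow(flt$records_q) == 0L) next
    prop <- suppressWarnings(
      propagate_annotations(rbind(flt$records_p, flt$records_q), dag))
    tp <- prop$sets[[pairs$gene_a[k]]]
    tq <- prop$sets[[pairs$gene_b[k]]]
    if (is.null(tp) || is.null(tq)) next
    fs[k] <- maryland_bridge(tp, tq)$value
  }
  pairs$fs <- fs
  pairs
}
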