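#' Maryland bridge functional similarity between two term sets
#'
#' Computes the set-overlap similarity
#' \deqn{fs(p, q) = \frac{|T(p) \cap T(q)|}{2}\left(\frac{1}{|T(p)|} + \frac{1}{|T(q)|}\right)}
#' between the propagated annotation term sets of two proteins. The value is
#' the average of the fraction of `p`'s terms recovered when transferring all
#' of `q`'s terms to `p`, and vice versa. It is 1 exactly for identical
#' non-empty sets and 0 exactly for disjoint sets, and always dominates the
#' Jaccard coefficient.
#'
#' Both sets must be non-empty: proteins with no (root-excluded) propagated
#' annotation in a namespace must be excluded from that namespace's analysis
#' upstream.
#'
#' @param t_p,t_q character vectors of term identifiers (duplicates ignored).
#' @return an object of class `similarity_score`: a list with elements
#'   `value`, `size_p`, `size_q`, `intersection`.
#' @examples
#' maryland_bridge(c("a", "b", "c"), c("b", "c", "d"))$value
#' @seealso [jaccard()]
#' @export
maryland_bridge <- function(t_p, t_q) {
  t_p <- unique(as.character(t_p))
  t_q <- unique(as.character(t_q))
  if (length(t_p) == 0L || length(t_q) == 0L) {
    stop("maryland_bridge() requires non-empty term sets; ",
         "exclude unannotated proteins upstream")
  }
  i <- length(intersect(t_p, t_q))
  structure(
    list(
      value = 0.5 * i * (1 / length(t_p) + 1 / length(t_q)),
      size_p = length(t_p),
      size_q = length(t_q),
      intersection = i
    ),
    class = "similarity_score"
  )
}

#' Jaccard similarity between two term sets
#'
#' Size of the intersection over the size of the union. Reported alongside
#' the Maryland bridge coefficient; the two are highly correlated and
#' `jaccard(A, B) <= maryland_bridge(A, B)$value` for every pair of sets,
#' with equality iff the sets are identical or disjoint.
#'
#' @inheritParams maryland_bridge
#' @return numeric scalar in `[0, 1]`.
#' @export
jaccard <- function(t_p, t_q) {
  t_p <- unique(as.character(t_p))
  t_q <- unique(as.character(t_q))
  if (length(t_p) == 0L || length(t_q) == 0L) {
    stop("jaccard() requires non-empty term sets")
  }
  length(intersect(t_p, t_q)) / length(union(t_p, t_q))
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("functional similarity: %.4f (|T(p)| = %d, |T(q)| = %d, shared = %d)\n",
              x$value, x$size_p, x$size_q, x$intersection))
  invisible(x)
}

#' Functional similarity for a table of homolog pairs
#'
#' Applies [maryland_bridge()] and [jaccard()] to each pair; pairs where
#' either protein lacks a propagated annotation set in this namespace get
#' `NA` (they are excluded from that namespace's analysis, not errors).
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @param sets named list mapping protein id to its propagated term set
#'   (e.g. the `sets` element of [propagate_annotations()]).
#' @return `pairs` with added columns `fs`, `jaccard`, `size_a`, `size_b`,
#'   `n_shared`.
#' @export
pair_functional_similarity <- function(pairs, sets) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  n <- nrow(pairs)
  fs <- jac <- rep(NA_real_, n)
  sa <- sb <- sh <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    tp <- sets[[pairs$gene_a[k]]]
    tq <- sets[[pairs$gene_b[k]]]
    if (is.null(tp) || is.null(tq) || length(tp) == 0L || length(tq) == 0L) next
    s <- maryland_bridge(tp, tq)
    fs[k] <- s$value
    jac[k] <- jaccard(tp, tq)
    sa[k] <- s$size_p
    sb[k] <- s$size_q
    sh[k] <- s$intersection
  }
  pairs$fs <- fs
  pairs$jaccard <- jac
  pairs$size_a <- sa
  pairs$size_b <- sb
  pairs$n_shared <- sh
  pairs
}
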