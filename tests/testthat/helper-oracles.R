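# Independent brute-force oracles. These deliberately avoid the package's
# code paths: closure by fixpoint iteration over an edge list, alignment by
# exhaustive path enumeration, pair classification from Newick-independent
# parent maps, rank statistics by complete enumeration.

# --- ancestor closure -------------------------------------------------------

oracle_closure <- function(terms, parents, root) {
  out <- unique(terms)
  repeat {
    more <- unique(unlist(parents[out], use.names = FALSE))
    new <- setdiff(more, out)
    if (length(new) == 0L) break
    out <- c(out, new)
  }
  setdiff(out, root)
}

oracle_bfs_depth <- function(parents, root, term) {
  # children map from parents map
  kids <- list()
  for (ch in names(parents)) for (p in parents[[ch]]) kids[[p]] <- c(kids[[p]], ch)
  depth <- 0L
  frontier <- root
  seen <- root
  while (length(frontier)) {
    if (term %in% frontier) return(depth)
    frontier <- setdiff(unique(unlist(kids[frontier], use.names = FALSE)), seen)
    seen <- c(seen, frontier)
    depth <- depth + 1L
  }
  NA_integer_
}

# --- global alignment by exhaustive enumeration -----------------------------

# maximum score over all global alignments, affine gaps (first gap residue
# open+extend, later residues extend each), terminal gaps penalized
oracle_align_score <- function(a, b, sub, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, score + sub[ca[i], cb[j]], "M")
    }
    if (i <= length(ca)) {
      pen <- if (last == "X") ext else open + ext
      rec(i + 1L, j, score - pen, "X")
    }
    if (j <= length(cb)) {
      pen <- if (last == "Y") ext else open + ext
      rec(i, j + 1L, score - pen, "Y")
    }
  }
  rec(1L, 1L, 0, "M")
  best
}

# --- homolog classification -------------------------------------------------

# brute-force classifier over a plain parent-map representation
oracle_classify <- function(parent, species, events, leaves) {
  path_up <- function(x) {
    p <- x
    while (!is.na(parent[[p[length(p)]]])) p <- c(p, parent[[p[length(p)]]])
    p
  }
  tips_below <- function(node) {
    leaves[vapply(leaves, function(l) node %in% path_up(l), logical(1))]
  }
  res <- list()
  for (i in seq_len(length(leaves) - 1L)) {
    for (j in (i + 1L):length(leaves)) {
      pi <- path_up(leaves[i]); pj <- path_up(leaves[j])
      common <- intersect(pi, pj)
      # LCA: the common ancestor farthest from the root
      lca <- common[which.max(vapply(common, function(x) length(path_up(x)), numeric(1)))]
      ev <- events[[lca]]
      same <- species[[leaves[i]]] == species[[leaves[j]]]
      if (!same && ev == "speciation") {
        dup_below <- function(p) {
          seg <- p[seq_len(which(p == lca) - 1L)]
          seg <- setdiff(seg, leaves)
          any(vapply(seg, function(x) events[[x]] == "duplication", logical(1)))
        }
        cls <- if (dup_below(pi) || dup_below(pj)) "ortholog_1toMany" else "ortholog_1to1"
      } else if (same) {
        sub_species <- unique(unlist(species[tips_below(lca)]))
        cls <- if (ev == "duplication" && length(sub_species) == 1L) "inparalog"
               else "within_species_outparalog"
      } else {
        cls <- "between_species_outparalog"
      }
      a <- leaves[i]; b <- leaves[j]
      if (a > b) { t <- a; a <- b; b <- t }
      res[[length(res) + 1L]] <- data.frame(gene_a = a, gene_b = b, class = cls,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# enumerate all rooted binary topologies over a leaf label set, as nested
# lists; unordered splits are enumerated via subsets containing the first
# element
all_topologies <- function(labels) {
  if (length(labels) == 1L) return(list(labels))
  out <- list()
  rest <- labels[-1L]
  for (k in 0:(length(rest) - 1L)) {
    combos <- if (k == 0) list(integer(0)) else utils::combn(length(rest), k, simplify = FALSE)
    for (cc in combos) {
      left <- c(labels[1L], rest[cc])
      right <- setdiff(labels, left)
      if (length(right) == 0L) next
      for (lt in all_topologies(left)) for (rt in all_topologies(right)) {
        out[[length(out) + 1L]] <- list(lt, rt)
      }
    }
  }
  out
}

# turn a nested-list topology plus event labels into (newick, parent-map)
topology_to_tree <- function(topo, events_draw) {
  counter <- new.env(); counter$n <- 0L
  parent <- list(); events <- list()
  build <- function(node, par) {
    if (is.character(node)) {
      parent[[node]] <<- par
      return(node)
    }
    counter$n <- counter$n + 1L
    id <- paste0("N", counter$n)
    parent[[id]] <<- par
    events[[id]] <<- events_draw(counter$n)
    for (kid in node) build(kid, id)
    id
  }
  build(topo, NA_character_)
  # rebuild newick recursively from topo alongside event labels
  counter$n <- 0L
  nw <- function(node) {
    if (is.character(node)) return(node)
    counter$n <- counter$n + 1L
    ev <- events[[paste0("N", counter$n)]]
    tag <- if (ev == "duplication") "[&&NHX:D=Y]" else "[&&NHX:D=N]"
    inner <- paste(vapply(node, nw, character(1)), collapse = ",")
    paste0("(", inner, ")", tag)
  }
  list(newick = paste0(nw(topo), ";"), parent = parent, events = events)
}

# --- rank statistics --------------------------------------------------------

# two-sided rank-sum p by bitmask enumeration over group assignments
oracle_ranksum_p <- function(ya, yb) {
  r <- rank(c(ya, yb))
  n <- length(r); na <- length(ya)
  mu <- na * (n + 1) / 2
  obs <- abs(sum(r[seq_len(na)]) - mu)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    if (sum(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L)) != na) next
    sel <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
    total <- total + 1L
    if (abs(sum(r[sel]) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Spearman rho via midranks, and two-sided permutation p by full enumeration
oracle_spearman <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  perms <- all_perms(length(y))
  rx <- rank(x)
  rhos <- vapply(perms, function(p) stats::cor(rx, rank(y)[p]), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}
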