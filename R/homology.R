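#' Parse a gene tree with duplication/speciation tags
#'
#' Reads one Newick string carrying NHX-style `[&&NHX:D=Y]` / `[&&NHX:D=N]`
#' tags on internal nodes (Y = duplication, N = speciation). Untagged internal
#' nodes are marked `"unlabeled"`; [label_events_species_overlap()] can then
#' assign them events from the species composition of their subtrees. Every
#' leaf must resolve in `gene_table`.
#'
#' @param newick_text a single Newick string.
#' @param gene_table data frame with columns `gene_id`, `species`,
#'   `chromosome`.
#' @return an [ape::phylo] tree with attributes `node_event` (character,
#'   one of `"speciation"`, `"duplication"`, `"unlabeled"`, indexed by
#'   internal node number minus `Ntip`) and `leaf_species` (named by leaf).
#' @export
parse_gene_tree <- function(newick_text, gene_table) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  txt <- gsub("\\[&&NHX:D=Y\\]", "NHXTAGDUP", newick_text)
  txt <- gsub("\\[&&NHX:D=N\\]", "NHXTAGSPE", txt)
  if (grepl("\\[", txt)) stop("malformed NHX comment in tree: ", newick_text)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick: ", newick_text)
  }
  missing <- setdiff(tree$tip.label, gene_table$gene_id)
  if (length(missing)) {
    stop("tree leaf/leaves not in gene table: ", paste(missing, collapse = ", "))
  }
  ev <- rep("unlabeled", tree$Nnode)
  if (!is.null(tree$node.label)) {
    ev[grepl("NHXTAGDUP$", tree$node.label)] <- "duplication"
    ev[grepl("NHXTAGSPE$", tree$node.label)] <- "speciation"
    tree$node.label <- sub("NHXTAG(DUP|SPE)$", "", tree$node.label)
  }
  attr(tree, "node_event") <- ev
  attr(tree, "leaf_species") <- stats::setNames(
    gene_table$species[match(tree$tip.label, gene_table$gene_id)],
    tree$tip.label)
  tree
}

#' Label tree events by species overlap
#'
#' A node is a duplication iff the species sets of its child subtrees
#' intersect, otherwise a speciation. By default only `"unlabeled"` nodes
#' are relabeled (explicit tags win); `relabel = TRUE` forces species-overlap
#' labeling everywhere.
#'
#' @param tree a tree from [parse_gene_tree()].
#' @param relabel overwrite existing tags.
#' @return the tree with a fully populated `node_event` attribute.
#' @export
label_events_species_overlap <- function(tree, relabel = FALSE) {
  ev <- attr(tree, "node_event")
  species <- attr(tree, "leaf_species")
  ntip <- ape::Ntip(tree)
  tipsets <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode), type = "tips")
  for (i in seq_len(tree$Nnode)) {
    if (!relabel && ev[i] != "unlabeled") next
    node <- ntip + i
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sets <- lapply(kids, function(k) {
      if (k <= ntip) species[tree$tip.label[k]]
      else unique(species[tree$tip.label[tipsets[[k - ntip]]]])
    })
    overlap <- FALSE
    if (length(sets) >= 2) {
      for (a in seq_len(length(sets) - 1L)) {
        for (b in (a + 1L):length(sets)) {
          if (length(intersect(sets[[a]], sets[[b]]))) overlap <- TRUE
        }
      }
    }
    ev[i] <- if (overlap) "duplication" else "speciation"
  }
  attr(tree, "node_event") <- ev
  tree
}

#' Evolutionary classes of homologous pairs
#' @return character vector of the five class labels.
#' @export
homolog_classes <- function() {
  c("ortholog_1to1", "ortholog_1toMany", "inparalog",
    "within_species_outparalog", "between_species_outparalog")
}

#' Classify every leaf pair of a gene tree
#'
#' For each unordered pair of leaves the class is decided by the event at
#' their last common ancestor (LCA) and the species of the two genes:
#' \itemize{
#' \item cross-species pair, speciation LCA: ortholog. One-to-one iff neither
#'   leaf has a duplication node strictly between itself and the LCA
#'   (otherwise one side carries inparalogs of the other's ortholog, giving
#'   one-to-many / many-to-many orthology);
#' \item same-species pair whose LCA subtree contains a single species:
#'   inparalog (the duplication postdates the species split on that lineage);
#' \item same-species pair whose LCA subtree contains both species:
#'   within-species outparalog;
#' \item cross-species pair, duplication LCA: between-species outparalog.
#' }
#' With two species these rules guarantee that within-species pairs can never
#' be confused with between-species pairs, whatever the tree topology.
#'
#' @param tree event-labeled tree ([parse_gene_tree()] +
#'   [label_events_species_overlap()] if tags were missing).
#' @param family_id identifier copied to every pair.
#' @return data frame: `gene_a`, `gene_b`, `class`, `family_id`. Pairs are
#'   unordered; `gene_a < gene_b` lexicographically.
#' @export
classify_homolog_pairs <- function(tree, family_id = NA_character_) {
  ev <- attr(tree, "node_event")
  if (is.null(ev) || any(ev == "unlabeled")) {
    stop("all internal nodes must be event-labeled before classification")
  }
  species <- attr(tree, "leaf_species")
  ntip <- ape::Ntip(tree)
  if (ntip < 2) return(data.frame(gene_a = character(0), gene_b = character(0),
                                  class = character(0), family_id = character(0)))
  labs <- tree$tip.label
  lca <- ape::mrca(tree)
  anc <- phangorn::Ancestors(tree, seq_len(ntip), type = "all")
  tipsets <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode), type = "tips")
  clade_species <- lapply(tipsets, function(tt) unique(species[labs[tt]]))
  res <- vector("list", ntip * (ntip - 1L) / 2L)
  k <- 0L
  for (i in seq_len(ntip - 1L)) {
    for (j in (i + 1L):ntip) {
      k <- k + 1L
      node <- lca[i, j]
      event <- ev[node - ntip]
      same_sp <- species[labs[i]] == species[labs[j]]
      if (!same_sp) {
        if (event == "speciation") {
          dup_between <- function(tip) {
            path <- anc[[tip]]
            path <- path[seq_len(which(path == node) - 1L)]  # strictly below LCA
            any(ev[path - ntip] == "duplication")
          }
          cls <- if (dup_between(i) || dup_between(j)) "ortholog_1toMany" else "ortholog_1to1"
        } else {
          cls <- "between_species_outparalog"
        }
      } else {
        single_species <- length(clade_species[[node - ntip]]) == 1L
        cls <- if (event == "duplication" && single_species) "inparalog"
               else "within_species_outparalog"
      }
      a <- labs[i]; b <- labs[j]
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      res[[k]] <- data.frame(gene_a = a, gene_b = b, class = cls,
                             family_id = family_id, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Merge apparent one-to-one orthologs into the 1:1 class
#'
#' Tree sources sometimes flag pairs as "apparent" 1:1 orthologs when the
#' topology is ambiguous. With `keep = TRUE` (default) these are treated as
#' ordinary one-to-one orthologs; with `keep = FALSE` they are removed from
#' the table so they cannot enter ortholog curves.
#'
#' @param pairs pair table with optional logical column `apparent`.
#' @param keep treat apparent pairs as `ortholog_1to1`.
#' @return the adjusted pair table.
#' @export
treat_apparent_orthologs <- function(pairs, keep = TRUE) {
  if (is.null(pairs$apparent)) return(pairs)
  app <- !is.na(pairs$apparent) & pairs$apparent
  if (keep) {
    pairs$class[app] <- "ortholog_1to1"
    pairs
  } else {
    pairs[!app, , drop = FALSE]
  }
}

#' Read gene metadata
#' @param path TSV with columns `gene_id`, `species`, `chromosome`.
#' @return data frame.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  need <- c("gene_id", "species", "chromosome")
  if (!all(need %in% names(g))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(g$species)) > 2) {
    stop("the analysis is defined for exactly two species; found ",
         length(unique(g$species)))
  }
  g
}

#' Classify homolog pairs for a whole forest
#'
#' Reads one Newick tree per line, labels any untagged nodes by species
#' overlap, and classifies every within-tree leaf pair. Family ids are
#' `F0001`, `F0002`, ... in file order.
#'
#' @param tree_file path to a Newick file (one tree per line).
#' @param gene_table data frame from [read_gene_table()].
#' @param relabel force species-overlap labeling everywhere.
#' @return data frame of classified pairs across all families.
#' @export
classify_forest <- function(tree_file, gene_table, relabel = FALSE) {
  lines <- readLines(tree_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tree <- parse_gene_tree(lines[i], gene_table)
    tree <- label_events_species_overlap(tree, relabel = relabel)
    out[[i]] <- classify_homolog_pairs(tree, family_id = sprintf("F%04d", i))
  }
  do.call(rbind, out)
}
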