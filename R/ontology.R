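#' Load one namespace of an OBO 1.2 ontology as a DAG
#'
#' Parses `[Term]` stanzas from an OBO 1.2 file, keeps the requested
#' namespace, drops obsolete terms, restricts edges to the requested relation
#' kinds (GO convention: `is_a` and `part_of`), and verifies the result is a
#' single-rooted acyclic graph. Edges are stored child-to-parent.
#'
#' @param path path to an OBO file.
#' @param namespace `"biological_process"` or `"molecular_function"` (any
#'   namespace string present in the file is accepted).
#' @param relations relation kinds followed as edges. `is_a` lines are always
#'   relation `"is_a"`; `relationship:` lines contribute their own type.
#' @return an object of class `ontology_dag`: list with `terms` (character),
#'   `parents` (named list, child -> parent ids), `root`, `namespace`,
#'   `graph` (an igraph, edges child->parent), `names` (term names).
#' @export
load_obo <- function(path, namespace = "biological_process",
                     relations = c("is_a", "part_of")) {
  stopifnot(length(namespace) == 1L)
  lines <- readLines(path, warn = FALSE)
  # split into stanzas
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) stop("not an OBO file (no stanzas): ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  term_ids <- character(0)
  term_names <- character(0)
  edge_child <- character(0)
  edge_parent <- character(0)
  edge_rel <- character(0)
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[starts[s]:ends[s]]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v)) v else NA_character_
    }
    if (!is.na(get1("is_obsolete")[1]) && get1("is_obsolete")[1] == "true") next
    ns <- get1("namespace")[1]
    if (!identical(ns, namespace)) next
    id <- get1("id")[1]
    if (is.na(id)) next
    term_ids <- c(term_ids, id)
    term_names <- c(term_names, get1("name")[1])
    isa <- grep("^is_a:", block, value = TRUE)
    for (l in isa) {
      p <- sub("^is_a: *", "", l)
      p <- trimws(sub("!.*$", "", p))
      edge_child <- c(edge_child, id); edge_parent <- c(edge_parent, p)
      edge_rel <- c(edge_rel, "is_a")
    }
    rel <- grep("^relationship:", block, value = TRUE)
    for (l in rel) {
      f <- strsplit(trimws(sub("!.*$", "", sub("^relationship: *", "", l))), "[ \t]+")[[1]]
      if (length(f) >= 2) {
        edge_child <- c(edge_child, id); edge_parent <- c(edge_parent, f[2])
        edge_rel <- c(edge_rel, f[1])
      }
    }
  }
  if (length(term_ids) == 0L) stop("no terms in namespace '", namespace, "' in ", path)
  keep <- edge_rel %in% relations & edge_child %in% term_ids & edge_parent %in% term_ids
  edge_child <- edge_child[keep]; edge_parent <- edge_parent[keep]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edge_child, to = edge_parent, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = term_ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    cyc <- tryCatch({
      comp <- igraph::components(g, mode = "strong")
      paste(names(comp$membership)[comp$membership %in%
        which(comp$csize > 1)][seq_len(min(10, sum(comp$csize[comp$csize > 1])))],
        collapse = ", ")
    }, error = function(e) "unknown")
    stop("ontology contains a cycle involving: ", cyc)
  }
  roots <- term_ids[igraph::degree(g, v = term_ids, mode = "out") == 0L]
  if (length(roots) != 1L) {
    stop("namespace '", namespace, "' must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  }
  # every non-root term must reach the root
  reach <- igraph::subcomponent(g, roots, mode = "in")$name
  orphan <- setdiff(term_ids, reach)
  if (length(orphan)) {
    stop("terms with no path to root ", roots, ": ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  parents <- split(edge_parent, factor(edge_child, levels = term_ids))
  structure(
    list(terms = term_ids, parents = parents, root = roots,
         namespace = namespace, graph = g,
         names = stats::setNames(term_names, term_ids)),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d edges, namespace %s, root %s\n",
              length(x$terms), igraph::ecount(x$graph), x$namespace, x$root))
  invisible(x)
}

#' All ancestors of a term (excluding the term itself)
#' @param dag an `ontology_dag`.
#' @param term a term id present in `dag`.
#' @return character vector of ancestor term ids (root included).
#' @export
dag_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"), term %in% dag$terms)
  setdiff(igraph::subcomponent(dag$graph, term, mode = "out")$name, term)
}

#' Read a GAF-like annotation table
#'
#' Tab-separated with columns `protein_id`, `species`, `term_id`,
#' `evidence_code`, `pubmed_ids` (semicolon-separated publication ids).
#'
#' @param path file path.
#' @return data frame with those five columns (`pubmed_ids` kept as the raw
#'   semicolon-separated string).
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  need <- c("protein_id", "species", "term_id", "evidence_code", "pubmed_ids")
  if (!all(need %in% names(ann))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(ann$evidence_code), go_evidence_codes())
  if (length(bad)) stop("unknown evidence code(s): ", paste(bad, collapse = ", "))
  ann[need]
}

#' The curated GO evidence codes admitted by the analysis
#'
#' Experimental codes (IDA, IEP, IGI, IMP, IPI) plus traceable author
#' statement (TAS) and curator inference (IC).
#' @return character vector.
#' @export
go_evidence_codes <- function() c("IDA", "IEP", "IGI", "IMP", "IPI", "TAS", "IC")

#' Propagate annotations towards the root of the DAG
#'
#' Each protein's term set T(p) is the union of its directly annotated terms
#' and all of their ancestors, with the root excluded, so that comparisons
#' between proteins are made on ancestor-closed sets. Records whose term is
#' not in the DAG are skipped with a warning (annotation releases drift
#' relative to ontology releases). Proteins whose propagated set is empty
#' (i.e. annotated only with the root) are dropped.
#'
#' @param records data frame as returned by [read_annotations()] (only
#'   `protein_id` and `term_id` are required).
#' @param dag an `ontology_dag`.
#' @return list with `sets` (named list protein -> character vector of terms,
#'   ancestor-closed, root excluded), `direct` (the used records), and
#'   `n_skipped` (records with unknown terms).
#' @export
propagate_annotations <- function(records, dag) {
  stopifnot(inherits(dag, "ontology_dag"), is.data.frame(records))
  known <- records$term_id %in% dag$terms
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(sprintf("skipping %d annotation record(s) with terms absent from the %s DAG",
                    n_skipped, dag$namespace))
  }
  records <- records[known, , drop = FALSE]
  # closure per distinct term, then union per protein
  terms_used <- unique(records$term_id)
  closure <- lapply(terms_used, function(t) {
    setdiff(c(t, dag_ancestors(dag, t)), dag$root)
  })
  names(closure) <- terms_used
  sets <- lapply(split(records$term_id, records$protein_id), function(tt) {
    unique(unlist(closure[unique(tt)], use.names = FALSE))
  })
  sets <- sets[lengths(sets) > 0L]
  list(sets = sets, direct = records, n_skipped = n_skipped)
}

#' Depth of terms in the ontology
#'
#' Distance from the root, following edges parent-to-child. By default the
#' shortest path is used; `method = "longest"` gives the longest path over
#' the DAG (both are in use in the literature and the choice matters for
#' depth-based truncation). `depth(root) = 0`.
#'
#' @param dag an `ontology_dag`.
#' @param terms term ids (default: all terms).
#' @param method `"shortest"` or `"longest"`.
#' @return named integer vector of depths.
#' @export
term_depth <- function(dag, terms = dag$terms, method = c("shortest", "longest")) {
  method <- match.arg(method)
  stopifnot(inherits(dag, "ontology_dag"))
  missing <- setdiff(terms, dag$terms)
  if (length(missing)) stop("unknown term(s): ", paste(missing, collapse = ", "))
  if (method == "shortest") {
    d <- igraph::distances(dag$graph, v = terms, to = dag$root, mode = "out")[, 1]
    return(stats::setNames(as.integer(d), terms))
  }
  # longest path from root: DP over a topological order (root first)
  ord <- igraph::topo_sort(dag$graph, mode = "in")$name
  depth <- stats::setNames(rep(-Inf, length(dag$terms)), dag$terms)
  depth[dag$root] <- 0
  for (v in ord) {
    if (v == dag$root) next
    p <- dag$parents[[v]]
    if (length(p)) depth[v] <- max(depth[p]) + 1
  }
  stats::setNames(as.integer(depth[terms]), terms)
}
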