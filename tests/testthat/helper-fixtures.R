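# Small fixtures built in code: ontology files and hand-drawn gene trees.

obo_file <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), f)
  f
}

term_stanza <- function(id, ns = "biological_process", parents = character(0),
                        rel = "is_a", obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: name ", id),
    paste0("namespace: ", ns),
    vapply(parents, function(p) {
      if (rel == "is_a") paste0("is_a: ", p) else
        paste0("relationship: ", rel, " ", p)
    }, character(1)),
    if (obsolete) "is_obsolete: true",
    "")
}

# leaf -> mid -> root chain
chain_obo <- function() {
  obo_file(c(term_stanza("GO:0000001"),
             term_stanza("GO:0000002", parents = "GO:0000001"),
             term_stanza("GO:0000003", parents = "GO:0000002")))
}

# leaf with two parents p1, p2 that both point at the root (a diamond)
diamond_obo <- function() {
  obo_file(c(term_stanza("GO:0000001"),
             term_stanza("GO:0000010", parents = "GO:0000001"),
             term_stanza("GO:0000011", parents = "GO:0000001"),
             term_stanza("GO:0000020", parents = c("GO:0000010", "GO:0000011"))))
}

# random single-rooted DAG as an ontology_dag plus its raw edge list
random_dag <- function(n_terms = 25, p_extra = 0.3) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- list()
  lines <- term_stanza(ids[1])
  for (i in 2:n_terms) {
    p <- ids[sample.int(i - 1L, 1L)]
    extra <- if (stats::runif(1) < p_extra && i > 2) {
      setdiff(ids[sample.int(i - 1L, 1L)], p)
    } else character(0)
    parents[[ids[i]]] <- c(p, extra)
    lines <- c(lines, term_stanza(ids[i], parents = c(p, extra)))
  }
  list(file = obo_file(lines), ids = ids, parents = parents, root = ids[1])
}

two_species_genes <- function(ids) {
  data.frame(gene_id = ids,
             species = ifelse(grepl("^H", ids), "human", "mouse"),
             chromosome = "chr1", stringsAsFactors = FALSE)
}

# the two canonical six- and four-gene topologies used throughout:
# (A) a one-to-many family with nested human duplications plus an older
#     duplicate pair, (B) two one-to-one ortholog pairs below a duplication
tree_one_to_many <- function() {
  "(((H1:1,(H2:0.5,H3:0.5)[&&NHX:D=Y]:0.5)[&&NHX:D=Y]:1,M1:2)[&&NHX:D=N]:1,(H4:2,M2:2)[&&NHX:D=N]:1)[&&NHX:D=Y];"
}
tree_two_one_to_one <- function() {
  "((H1:1,M1:1)[&&NHX:D=N]:1,(H2:1,M2:1)[&&NHX:D=N]:1)[&&NHX:D=Y];"
}

make_ann <- function(protein_id, term_id, species = "human",
                     evidence_code = "IDA", pubmed_ids = "PM1") {
  data.frame(protein_id = protein_id, species = species, term_id = term_id,
             evidence_code = evidence_code, pubmed_ids = pubmed_ids,
             stringsAsFactors = FALSE)
}
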