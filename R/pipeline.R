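# End-to-end orchestration: annotate -> classify -> align -> expression ->
# functional similarity -> pair table, plus curve/family outputs and a run
# manifest. All randomness flows from the single seed argument.

read_fasta_chars <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub(" .*$", "", names(x))
  out
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Expects the file layout written by [write_dataset()] (ontology, gene
#' table, NHX-tagged trees, protein and coding FASTA, annotation TSV,
#' expression TSV with probe and transcript FASTA, shared-tissue list).
#' Stages: load and propagate annotations per namespace; classify homolog
#' pairs from the gene trees; align all pairs (identity, dN/dS); map probes,
#' normalize expression in two steps, collapse probesets and duplicate
#' tissues, and correlate profiles; score functional similarity per
#' namespace; assemble the pair table. Writes `pair_table.tsv`,
#' `curve_*.tsv`, `family_analysis_*.tsv` and `manifest.json` under
#' `out_dir`.
#'
#' @param input_dir dataset directory.
#' @param out_dir output directory (created).
#' @param seed integer seed (used for the family-analysis target draws).
#' @param compute_dnds estimate dN/dS for all pairs (the slowest stage
#'   after alignment; curves on the identity axis do not need it).
#' @param family_reps replicates of the family-based analysis.
#' @return (invisibly) a list with `pair_table`, `sets` (per namespace),
#'   `records`, `dags`, `expr`, `family` (per namespace), `manifest`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, seed = 1,
                         compute_dnds = TRUE, family_reps = 100L) {
  need <- c("ontology.obo", "genes.tsv", "trees.nwk", "proteins.fa", "cds.fa",
            "annotations.tsv", "expression.tsv", "probes.fa", "transcripts.fa",
            "tissues.txt")
  paths <- file.path(input_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))

  genes <- read_gene_table(file.path(input_dir, "genes.tsv"))
  ann <- utils::read.delim(file.path(input_dir, "annotations.tsv"),
                           stringsAsFactors = FALSE, colClasses = "character")
  dags <- list(BP = load_obo(file.path(input_dir, "ontology.obo"), "biological_process"),
               MF = load_obo(file.path(input_dir, "ontology.obo"), "molecular_function"))
  ns_col <- if ("namespace" %in% names(ann)) ann$namespace else {
    ifelse(ann$term_id %in% dags$BP$terms, "BP", "MF")
  }
  records <- list(BP = ann[ns_col == "BP", , drop = FALSE],
                  MF = ann[ns_col == "MF", , drop = FALSE])
  sets <- list(BP = propagate_annotations(records$BP, dags$BP)$sets,
               MF = propagate_annotations(records$MF, dags$MF)$sets)

  pairs <- classify_forest(file.path(input_dir, "trees.nwk"), genes)
  pairs <- treat_apparent_orthologs(pairs)

  proteins <- read_fasta_chars(file.path(input_dir, "proteins.fa"), "AA")
  cds <- if (compute_dnds) read_fasta_chars(file.path(input_dir, "cds.fa"), "DNA") else NULL
  seq_res <- align_pairs(pairs[c("gene_a", "gene_b")], proteins, cds)

  fs_bp <- pair_functional_similarity(pairs[c("gene_a", "gene_b")], sets$BP)
  fs_mf <- pair_functional_similarity(pairs[c("gene_a", "gene_b")], sets$MF)

  expr <- pipeline_expression(input_dir, pairs)

  tab <- assemble_pair_table(pairs, seq_res, fs_bp, fs_mf, expr$pair_cor, genes)

  fam <- list(BP = run_family_analysis(tab, "fs_BP", family_reps, seed),
              MF = run_family_analysis(tab, "fs_MF", family_reps, seed + 1))

  manifest <- list(
    seed = seed,
    inputs = as.list(tools::md5sum(paths)),
    tool_version = as.character(utils::packageVersion("orthoconj")),
    counts = list(
      genes = nrow(genes), pairs = nrow(tab),
      pairs_per_class = as.list(table(tab$class)),
      annotated_BP = length(sets$BP), annotated_MF = length(sets$MF),
      probesets_mapped = nrow(expr$map),
      probesets_rejected = nrow(attr(expr$map, "rejections"))
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "pair_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (ns in c("BP", "MF")) {
      cv <- bin_curve(tab, "identity", paste0("fs_", ns), classes = "ortholog_1to1")
      utils::write.table(as.data.frame(cv),
                         file.path(out_dir, paste0("curve_ortholog_", ns, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cvp <- bin_curve(tab, "identity", paste0("fs_", ns),
                       classes = paralog_class_set())
      utils::write.table(as.data.frame(cvp),
                         file.path(out_dir, paste0("curve_paralog_", ns, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fc <- fam[[ns]]
      utils::write.table(
        data.frame(cell = colnames(fc$replicates),
                   mean = colMeans(fc$replicates),
                   se = apply(fc$replicates, 2, stats::sd) / sqrt(fc$n_reps)),
        file.path(out_dir, paste0("family_analysis_", ns, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(pair_table = tab, sets = sets, records = records, dags = dags,
                 expr = expr, family = fam, manifest = manifest))
}

pipeline_expression <- function(input_dir, pairs) {
  em <- utils::read.delim(file.path(input_dir, "expression.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(em[, -1, drop = FALSE])
  rownames(mat) <- em[[1]]
  colnames(mat) <- names(em)[-1]
  probes <- read_fasta_chars(file.path(input_dir, "probes.fa"), "DNA")
  transcripts <- read_fasta_chars(file.path(input_dir, "transcripts.fa"), "DNA")
  tissues <- readLines(file.path(input_dir, "tissues.txt"), warn = FALSE)
  map <- map_probes_to_genes(probes, transcripts)
  norm <- normalize_two_step(mat)
  gene_mat <- collapse_probesets(norm$n, map)
  gene_mat <- gene_mat[, colnames(gene_mat) %in% tissues, drop = FALSE]
  gene_mat <- average_duplicate_tissues(gene_mat)
  pc <- pairs[c("gene_a", "gene_b")]
  pc$expr_cor <- vapply(seq_len(nrow(pc)), function(k) {
    expression_similarity(gene_mat, pc$gene_a[k], pc$gene_b[k], tissues)
  }, numeric(1))
  list(map = map, norm = norm, gene_matrix = gene_mat, pair_cor = pc)
}
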