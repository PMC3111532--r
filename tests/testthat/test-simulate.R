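small_cfg <- function(...) {
  sim_config(n_families = 12, n_terms_bp = 60, n_terms_mf = 40, ...)
}

test_that("generated ontologies always pass OBO validation", {
  set.seed(1)
  ont <- generate_ontology(3, prefix = "BP")
  expect_equal(length(ont$terms$id), 3)
  expect_equal(ont$root, "BP:00001")
  expect_equal(nrow(ont$edges[ont$edges$parent == ont$root, ]), 2)
  for (s in 1:4) {
    set.seed(s)
    ont <- generate_ontology(50, prefix = "BP", p_extra_parent = 0.4)
    f <- tempfile(fileext = ".obo")
    write_obo(list(ont), f)
    dag <- load_obo(f)
    expect_setequal(dag$terms, ont$terms$id)
    expect_equal(dag$root, ont$root)
  }
})

test_that("a zero duplication rate yields pure one-to-one ortholog families", {
  set.seed(2)
  cfg <- small_cfg(dup_rate = 0)
  for (i in 1:5) {
    fam <- simulate_family(cfg, sprintf("F%04d", i))
    tr <- family_truth(fam, cfg)
    expect_equal(nrow(fam$genes), 2)
    expect_equal(tr$true_class, "ortholog_1to1")
    expect_equal(tr$divergence_time, 2 * (cfg$t_total - cfg$t_speciation))
  }
})

test_that("the inparalog fraction grows with the duplication rate", {
  frac <- function(rate, seed) {
    set.seed(seed)
    cfg <- sim_config(dup_rate = rate)
    cls <- character(0)
    for (i in 1:120) {
      tr <- family_truth(simulate_family(cfg, "F0001"), cfg)
      cls <- c(cls, tr$true_class)
    }
    mean(cls == "inparalog")
  }
  expect_gt(frac(0.6, 3), frac(0.1, 3))
})

test_that("event labels and ages in emitted trees match the topology classifier", {
  set.seed(4)
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  d <- tempfile(); write_dataset(ds, d)
  genes <- read_gene_table(file.path(d, "genes.tsv"))
  pairs <- classify_forest(file.path(d, "trees.nwk"), genes)
  tr <- ds$truth
  key <- function(x) paste(x$gene_a, x$gene_b)
  m <- match(key(tr), key(pairs))
  expect_false(anyNA(m))
  expect_equal(pairs$class[m], tr$true_class)
})

test_that("zero substitution rates copy sequences unchanged", {
  set.seed(5)
  cfg <- small_cfg(mu_nonsyn = 0, mu_syn = 0)
  fam <- simulate_family(cfg, "F0001")
  seqs <- evolve_sequences(fam, cfg)
  expect_equal(length(unique(seqs$cds)), 1L)
  expect_false(grepl("\\*", seqs$protein[[1]]))
})

test_that("protein identity decays with divergence time following the closed form", {
  set.seed(6)
  cfg <- sim_config(n_codons = 200)
  match_frac <- c(); expected <- c(); fam_resid <- c()
  for (i in 1:120) {
    fam <- simulate_family(cfg, "F0001")
    tr <- family_truth(fam, cfg)
    seqs <- evolve_sequences(fam, cfg)
    mf <- ex <- c()
    for (k in seq_len(nrow(tr))) {
      a <- strsplit(seqs$protein[[tr$gene_a[k]]], "")[[1]]
      b <- strsplit(seqs$protein[[tr$gene_b[k]]], "")[[1]]
      mf <- c(mf, mean(a == b))
      tau <- tr$divergence_time[k]
      ex <- c(ex, 1 / 20 + (19 / 20) * exp(-(20 / 19) * cfg$mu_nonsyn * tau))
    }
    match_frac <- c(match_frac, mf); expected <- c(expected, ex)
    fam_resid <- c(fam_resid, mean(mf - ex))
  }
  # pairs within a family share branches, so the Monte-Carlo error is taken
  # across independent families
  se <- sd(fam_resid) / sqrt(length(fam_resid))
  expect_lt(abs(mean(fam_resid)), 3 * se + 1e-9)
  # and the decay is monotone: younger pairs are more identical on average
  young <- match_frac[expected > median(expected)]
  old <- match_frac[expected <= median(expected)]
  expect_gt(mean(young), mean(old))
})

test_that("silent substitutions accumulate as dS while dN/dS stays moderate", {
  set.seed(7)
  cfg <- sim_config()
  ds_vals <- tau_vals <- c()
  for (i in 1:40) {
    fam <- simulate_family(cfg, "F0001")
    tr <- family_truth(fam, cfg)
    seqs <- evolve_sequences(fam, cfg)
    for (k in seq_len(nrow(tr))) {
      est <- estimate_divergence(seqs$cds[[tr$gene_a[k]]], seqs$cds[[tr$gene_b[k]]])
      if (!is.na(est$dS)) {
        ds_vals <- c(ds_vals, est$dS)
        tau_vals <- c(tau_vals, tr$divergence_time[k])
      }
    }
  }
  expect_gt(cor(ds_vals, tau_vals, method = "spearman"), 0.5)
})

test_that("without annotation turnover every homolog pair has full similarity", {
  set.seed(8)
  cfg <- small_cfg(lambda_gain = 0, lambda_loss = 0, delta = 0)
  ds <- simulate_dataset(cfg)
  dir <- tempfile(); write_dataset(ds, dir)
  dag <- load_obo(file.path(dir, "ontology.obo"), "biological_process")
  ann <- utils::read.delim(file.path(dir, "annotations.tsv"), stringsAsFactors = FALSE)
  sets <- propagate_annotations(ann[ann$namespace == "BP", ], dag)$sets
  fs <- pair_functional_similarity(ds$truth, sets)$fs
  expect_true(all(fs[!is.na(fs)] == 1))
})

test_that("annotation similarity declines with divergence time", {
  set.seed(9)
  cfg <- sim_config(n_families = 60, annotation_sparsity = 1)
  ds <- simulate_dataset(cfg)
  dir <- tempfile(); write_dataset(ds, dir)
  dag <- load_obo(file.path(dir, "ontology.obo"), "biological_process")
  ann <- utils::read.delim(file.path(dir, "annotations.tsv"), stringsAsFactors = FALSE)
  sets <- propagate_annotations(ann[ann$namespace == "BP", ], dag)$sets
  fs <- pair_functional_similarity(ds$truth, sets)$fs
  ok <- !is.na(fs)
  expect_lt(cor(fs[ok], ds$truth$divergence_time[ok], method = "spearman"), -0.3)
})

test_that("a frozen expression drift keeps all profiles perfectly correlated", {
  set.seed(10)
  cfg <- small_cfg(sigma2_expr = 0, delta = 0, measurement_sd = 0)
  fam <- simulate_family(cfg, "F0001")
  prof <- evolve_expression_profiles(fam, cfg)
  m <- do.call(rbind, prof)
  expect_true(all(abs(cor(t(m)) - 1) < 1e-12))
})

test_that("expression correlation decreases with divergence time", {
  set.seed(12)
  cfg <- sim_config()
  cors <- taus <- c()
  for (i in 1:80) {
    fam <- simulate_family(cfg, "F0001")
    tr <- family_truth(fam, cfg)
    prof <- evolve_expression_profiles(fam, cfg)
    for (k in seq_len(nrow(tr))) {
      cors <- c(cors, cor(prof[[tr$gene_a[k]]], prof[[tr$gene_b[k]]]))
      taus <- c(taus, tr$divergence_time[k])
    }
  }
  expect_lt(cor(cors, taus, method = "spearman"), -0.2)
})

test_that("planted ambiguous probesets are rejected by the mapping", {
  set.seed(13)
  cfg <- sim_config(n_families = 20, n_terms_bp = 60, n_terms_mf = 40,
                    p_ambiguous_probeset = 0.2)
  ds <- simulate_dataset(cfg)
  rej <- attr(map_probes_to_genes(ds$expression$probes, ds$expression$transcripts),
              "rejections")
  expect_true(all(ds$expression$ambiguous_probesets %in% rej$probeset_id))
})

test_that("the whole dataset is byte-identical across runs with one seed", {
  cfg <- small_cfg(seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  d3 <- tempfile()
  write_dataset(simulate_dataset(small_cfg(seed = 78)), d3)
  expect_false(all(tools::md5sum(file.path(d3, f1)) ==
                     tools::md5sum(file.path(d1, f1))))
})
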