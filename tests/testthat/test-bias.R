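test_that("terms absent from one species are removed everywhere", {
  sets <- list(h1 = c("t1", "t2"), h2 = c("t3"), m1 = c("t1", "t3"))
  species <- c(h1 = "human", h2 = "human", m1 = "mouse")
  out <- filter_shared_species_terms(sets, species)
  # t2 is human-only: removed; t1 and t3 occur in both species
  expect_setequal(out$sets$h1, "t1")
  expect_setequal(out$sets$h2, "t3")
  expect_setequal(out$sets$m1, c("t1", "t3"))
  expect_equal(out$report$records_before, 5)
  expect_equal(out$report$records_after, 4)
  # a protein emptied by the filter is dropped
  sets2 <- list(h1 = "t2", m1 = "t1")
  out2 <- filter_shared_species_terms(sets2, species)
  expect_equal(length(out2$sets), 0)
})

test_that("the shared-species filter is an idempotent contraction", {
  set.seed(19)
  for (rep in 1:5) {
    prots <- paste0("p", 1:10)
    species <- stats::setNames(rep(c("human", "mouse"), 5), prots)
    sets <- lapply(prots, function(p) sample(paste0("t", 1:12), sample(1:6, 1)))
    names(sets) <- prots
    once <- filter_shared_species_terms(sets, species)
    expect_lte(sum(lengths(once$sets)), sum(lengths(sets)))
    twice <- filter_shared_species_terms(once$sets, species)
    expect_identical(twice$sets, once$sets)
  }
})

test_that("family depth truncation generalizes to the shallowest-annotated member", {
  dag <- load_obo(chain_obo())  # depths: root 0, 0000002 1, 0000003 2
  sets <- list(p1 = c("GO:0000002", "GO:0000003"),  # max depth 2
               p2 = c("GO:0000002"))                 # max depth 1 -> d* = 1
  fams <- c(p1 = "f1", p2 = "f1")
  out <- truncate_family_depth(sets, fams, dag)
  expect_equal(out$sets$p1, "GO:0000002")
  expect_equal(out$sets$p2, "GO:0000002")
  # equal maximal depths leave everything unchanged
  sets2 <- list(p1 = c("GO:0000002", "GO:0000003"), p2 = c("GO:0000003"))
  out2 <- truncate_family_depth(sets2, fams, dag)
  expect_setequal(out2$sets$p1, sets2$p1)
})

test_that("depth truncation never empties an ancestor-closed set", {
  set.seed(29)
  for (rep in 1:6) {
    rd <- random_dag(20)
    dag <- load_obo(rd$file)
    prots <- paste0("p", 1:6)
    sets <- lapply(prots, function(p) {
      direct <- sample(rd$ids[-1], sample(1:3, 1))
      oracle_closure(direct, rd$parents, rd$root)
    })
    names(sets) <- prots
    fams <- stats::setNames(rep(c("f1", "f2"), 3), prots)
    out <- truncate_family_depth(sets, fams, dag)
    expect_true(all(lengths(out$sets) > 0))
    expect_true(all(mapply(function(a, b) all(a %in% b), out$sets, sets[names(out$sets)])))
  }
})

test_that("unavoidable same-publication support is dropped for the pair", {
  rp <- make_ann("p", "t1", pubmed_ids = "PM1")
  rq <- make_ann("q", "t2", pubmed_ids = "PM1")
  out <- pair_publication_filter(rp, rq)
  expect_equal(nrow(out$records_p), 0)
  expect_equal(nrow(out$records_q), 0)
  # a second publication id on one side reconciles both annotations
  rp2 <- make_ann("p", "t1", pubmed_ids = "PM1;PM2")
  out2 <- pair_publication_filter(rp2, rq)
  expect_equal(nrow(out2$records_p), 1)
  expect_equal(nrow(out2$records_q), 1)
})

test_that("the inverse mode keeps only same-publication support", {
  rp <- rbind(make_ann("p", "t1", pubmed_ids = "PM1"),
              make_ann("p", "t2", pubmed_ids = "PM9"))
  rq <- make_ann("q", "t3", pubmed_ids = "PM1")
  out <- pair_publication_filter(rp, rq, mode = "same_only")
  expect_equal(out$records_p$term_id, "t1")
  expect_equal(out$records_q$term_id, "t3")
})

test_that("dropping TAS removes those records before propagation", {
  rec <- rbind(make_ann("p", "t1", evidence_code = "TAS"),
               make_ann("p", "t2", evidence_code = "IDA"),
               make_ann("q", "t3", evidence_code = "TAS"))
  out <- restrict_evidence(rec)
  expect_equal(out$records$term_id, "t2")
  expect_equal(out$report$records_before, 3)
  expect_equal(out$report$records_after, 1)
  expect_false("q" %in% out$records$protein_id)  # TAS-only protein excluded
  bad <- make_ann("p", "t1", evidence_code = "XXX")
  expect_error(restrict_evidence(bad), "unknown evidence")
})

test_that("dropping TAS commutes with propagation", {
  set.seed(37)
  for (rep in 1:5) {
    rd <- random_dag(15)
    dag <- load_obo(rd$file)
    rec <- make_ann(rep("p", 5), sample(rd$ids[-1], 5),
                    evidence_code = sample(c("TAS", "IDA"), 5, TRUE))
    filtered <- restrict_evidence(rec)$records
    if (nrow(filtered) == 0) next
    direct_first <- propagate_annotations(filtered, dag)$sets[["p"]]
    # propagate everything, then remove the part of the closure supported
    # only by TAS annotations
    full <- propagate_annotations(rec, dag)$sets[["p"]]
    tas_only <- setdiff(full, oracle_closure(filtered$term_id, rd$parents, rd$root))
    expect_setequal(setdiff(full, tas_only), direct_first)
  }
})

test_that("same-evidence filtering keeps codes used by both proteins", {
  rp <- rbind(make_ann("p", "t1", evidence_code = "IDA"),
              make_ann("p", "t2", evidence_code = "TAS"))
  rq <- make_ann("q", "t3", evidence_code = "IDA")
  out <- pair_same_evidence_filter(rp, rq)
  expect_equal(out$records_p$term_id, "t1")
  expect_equal(out$records_q$term_id, "t3")
  # identical single-code pairs are fully retained
  out2 <- pair_same_evidence_filter(make_ann("p", "t1"), make_ann("q", "t2"))
  expect_equal(nrow(out2$records_p), 1)
  expect_equal(nrow(out2$records_q), 1)
  # per-protein mode requires identical code sets
  out3 <- pair_same_evidence_filter(rp, rq, per_protein = TRUE)
  expect_equal(nrow(out3$records_p), 0)
  out4 <- pair_same_evidence_filter(rq, rq, per_protein = TRUE)
  expect_equal(nrow(out4$records_p), 1)
})

test_that("per-pair filtered similarity re-propagates the surviving records", {
  dag <- load_obo(diamond_obo())
  rec <- rbind(
    make_ann("p", "GO:0000020", pubmed_ids = "PM1;PM2"),
    make_ann("q", "GO:0000020", pubmed_ids = "PM1"),
    make_ann("q", "GO:0000010", pubmed_ids = "PM3"))
  pairs <- data.frame(gene_a = "p", gene_b = "q", stringsAsFactors = FALSE)
  out <- pair_fs_filtered(pairs, rec, dag,
                          function(a, b) pair_publication_filter(a, b))
  # both GO:0000020 annotations survive via PM2/PM1 reassignment
  expect_equal(out$fs, 1 * 0.5 * (1 / 3 + 1 / 3) * 3)  # identical sets of size 3
  # if q loses its only reconcilable support the pair is NA
  rec2 <- rbind(make_ann("p", "GO:0000020", pubmed_ids = "PM1"),
                make_ann("q", "GO:0000010", pubmed_ids = "PM1"))
  out2 <- pair_fs_filtered(pairs, rec2, dag,
                           function(a, b) pair_publication_filter(a, b))
  expect_true(is.na(out2$fs))
})
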