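make_records <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
    class = sample(homolog_classes(), n, replace = TRUE),
    family_id = paste0("f", rep(1:8, length.out = n)),
    identity = runif(n, 0.5, 1), fs_BP = runif(n), fs_MF = runif(n),
    dN = NA_real_, dS = NA_real_, dn_ds = NA_real_,
    expr_cor = runif(n, -1, 1), same_chromosome = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE)
}

test_that("the pair table joins each measure by unordered pair", {
  pairs <- data.frame(gene_a = c("g1", "g2"), gene_b = c("g2x", "g3"),
                      class = c("ortholog_1to1", "inparalog"), family_id = "f1",
                      stringsAsFactors = FALSE)
  seqr <- data.frame(gene_a = c("g2x", "g2"), gene_b = c("g1", "g3"),
                     identity = c(0.9, 0.8), stringsAsFactors = FALSE)
  fsb <- data.frame(gene_a = "g1", gene_b = "g2x", fs = 0.5, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("g1", "g2", "g2x", "g3"),
                      species = c("human", "mouse", "mouse", "mouse"),
                      chromosome = c("chr1", "chr2", "chr1", "chr2"),
                      stringsAsFactors = FALSE)
  tab <- assemble_pair_table(pairs, seqr, fs_bp = fsb, gene_table = genes)
  expect_equal(tab$identity, c(0.9, 0.8))  # reversed key still joins
  expect_equal(tab$fs_BP, c(0.5, NA))
  expect_true(is.na(tab$fs_MF[1]))
  expect_true(is.na(tab$same_chromosome[1]))   # cross-species: undefined
  expect_true(tab$same_chromosome[2])          # g2-g3: mouse, chr2 == chr2
  # same-species pair on different chromosomes
  pairs3 <- data.frame(gene_a = "g2x", gene_b = "g3", class = "inparalog",
                       family_id = "f", stringsAsFactors = FALSE)
  seqr3 <- data.frame(gene_a = "g2x", gene_b = "g3", identity = 0.7,
                      stringsAsFactors = FALSE)
  tab3 <- assemble_pair_table(pairs3, seqr3, gene_table = genes)
  expect_false(tab3$same_chromosome[1])
  dup <- rbind(pairs, pairs[1, ])
  expect_error(assemble_pair_table(dup, seqr), "duplicate")
})

test_that("binned curves report n, mean and sd/sqrt(n) per half-open bin", {
  rec <- data.frame(class = "inparalog", identity = c(0.62, 0.62, 0.9),
                    fs_BP = c(0.2, 0.4, 0.7))
  cv <- bin_curve(rec, "identity", "fs_BP", edges = identity_bins())
  b1 <- cv[cv$bin_lo == 0.6, ]
  expect_equal(b1$n, 2)
  expect_equal(b1$mean, 0.3)
  expect_equal(b1$se, sd(c(0.2, 0.4)) / sqrt(2))
  b2 <- cv[cv$bin_lo == 0.9, ]
  expect_equal(b2$n, 1)
  expect_equal(b2$se, 0)
  expect_true(b2$se_flagged)
})

test_that("bin edges follow the half-open convention with a closed last bin", {
  rec <- data.frame(class = "inparalog", identity = c(0.65, 0.7, 1.0, 0.49),
                    fs_BP = c(1, 2, 3, 4))
  cv <- bin_curve(rec, "identity", "fs_BP")
  expect_equal(cv$n[cv$bin_lo == 0.65], 1)           # 0.65 in [0.65, 0.70)
  expect_equal(cv$mean[cv$bin_lo == 0.70], 2)        # 0.70 to the right bin
  expect_equal(cv$mean[cv$bin_lo == 0.95], 3)        # 1.0 in the closed last bin
  expect_equal(sum(cv$n), 3)                         # 0.49 excluded
})

test_that("every in-range record lands in exactly one bin", {
  rec <- make_records(200, seed = 3)
  cv <- bin_curve(rec, "identity", "fs_BP")
  expect_equal(sum(cv$n), sum(rec$identity >= 0.5 & rec$identity <= 1))
  expect_warning(bin_curve(rec[0, ], "identity", "fs_BP"), "no records")
})

test_that("small-sample rank-sum p-values match complete enumeration", {
  set.seed(17)
  for (rep in 1:12) {
    na <- sample(3:7, 1); nb <- sample(3:7, 1)
    # draw with ties to exercise midranks
    ya <- sample(1:5, na, replace = TRUE) / 5
    yb <- sample(1:5, nb, replace = TRUE) / 5 + 0.1
    rec <- data.frame(class = rep(c("A", "B"), c(na, nb)),
                      identity = 1, fs_BP = c(ya, yb))
    got <- compare_classes(rec, "A", "B", "fs_BP", identity_threshold = 0)
    expect_equal(got$method, "exact enumeration")
    expect_equal(got$p_value, oracle_ranksum_p(ya, yb), tolerance = 1e-12)
  }
})

test_that("class comparisons pool above the identity threshold and report direction", {
  set.seed(23)
  rec <- data.frame(
    class = rep(c("inparalog", "ortholog_1to1"), each = 60),
    identity = rep(c(0.6, 0.8), 60),
    fs_BP = c(rnorm(60, 0.8, 0.05), rnorm(60, 0.4, 0.05)))
  out <- compare_classes(rec, "inparalog", "ortholog_1to1", "fs_BP",
                         identity_threshold = 0.7)
  expect_equal(out$n_a, 30)   # only identity >= 0.7 pairs pool
  expect_equal(out$direction, 1)
  expect_lt(out$p_value, 1e-5)
  expect_error(compare_classes(rec, "inparalog", "nope", "fs_BP", 0),
               "no records for class")
})

test_that("the rank-sum test holds its size under the null", {
  set.seed(31)
  reject <- 0L
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    rec <- data.frame(class = rep(c("A", "B"), each = 40), identity = 1,
                      fs_BP = rnorm(80))
    p <- compare_classes(rec, "A", "B", "fs_BP", 0)$p_value
    if (p < 0.05) reject <- reject + 1L
  }
  expect_gt(reject / n_sim, 0.02)
  expect_lt(reject / n_sim, 0.09)
})

test_that("trend correlations use midranks and flag degenerate input", {
  rec <- data.frame(class = "inparalog", identity = 1:10 / 10, fs_BP = (1:10)^2)
  out <- trend_correlation(rec, x_variable = "identity", y_variable = "fs_BP")
  expect_equal(out$rho, 1)
  # ties handled via midranks: compare against a naive midrank computation
  set.seed(41)
  x <- sample(1:4, 30, TRUE); y <- sample(1:4, 30, TRUE)
  rec2 <- data.frame(class = "inparalog", identity = x, fs_BP = y)
  out2 <- trend_correlation(rec2, x_variable = "identity", y_variable = "fs_BP")
  expect_equal(out2$rho, stats::cor(rank(x), rank(y)))
  rec3 <- data.frame(class = "x", identity = rep(1, 5), fs_BP = rnorm(5))
  expect_true(trend_correlation(rec3, x_variable = "identity",
                                y_variable = "fs_BP")$undefined)
})

test_that("spearman p-values agree with permutation enumeration for small tie-free samples", {
  set.seed(43)
  for (n in c(5, 6)) {
    x <- sample(100, n); y <- sample(100, n)
    rec <- data.frame(class = "c", identity = x, fs_BP = y)
    got <- trend_correlation(rec, x_variable = "identity", y_variable = "fs_BP")
    orc <- oracle_spearman(x, y)
    expect_equal(got$rho, orc$rho, tolerance = 1e-12)
    expect_equal(got$p_value, orc$p, tolerance = 1e-9)
  }
})

test_that("chromosome split restricts to within-species paralogs and partitions them", {
  rec <- make_records(80, seed = 5)
  cs <- chromosome_split_curves(rec, "fs_BP")
  within <- rec[rec$class %in% c("inparalog", "within_species_outparalog") &
                  !is.na(rec$same_chromosome) &
                  rec$identity >= 0.5, ]
  expect_equal(sum(cs$same$n) + sum(cs$different$n), nrow(within))
  rec2 <- rec[rec$class == "inparalog", ]
  rec2$same_chromosome <- TRUE
  expect_warning(cs2 <- chromosome_split_curves(rec2, "fs_BP"), "no records")
  expect_equal(nrow(cs2$different), 0)
})

test_that("matched-bin comparison recovers a planted constant shift", {
  set.seed(47)
  n <- 300
  rec <- data.frame(
    class = rep(c("A", "B"), each = n),
    identity = runif(2 * n, 0.5, 1))
  rec$fs_BP <- 1 - rec$identity + ifelse(rec$class == "A", 0.08, 0) + rnorm(2 * n, 0, 0.05)
  out <- compare_classes_matched(rec, "A", "B", "fs_BP")
  expect_equal(out$direction, 1)
  expect_lt(out$p_value, 1e-6)
  expect_error(compare_classes_matched(rec[rec$identity < 0.55, ], "A", "B",
                                       "fs_BP", min_per_class = 1e6),
               "no bins")
})
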