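test_that("self-alignment is all matches and identity 1", {
  a <- global_align("MKTAYIAKQR", "MKTAYIAKQR")
  expect_equal(a$matches, 10)
  expect_equal(a$length, 10)
  expect_equal(percent_identity(a), 1.0)
})

test_that("a one-residue overhang forces a single gap column", {
  a <- global_align("AC", "A")
  expect_equal(a$length, 2)
  expect_equal(a$matches, 1)
  expect_equal(a$aligned_b, "A-")
})

test_that("empty and illegal sequences are rejected with positions", {
  expect_error(global_align("", "MK"), "non-empty")
  expect_error(global_align("MKB", "MK"), "'B' at position 3")
  expect_error(global_align("MK", "M1K"), "position 2")
})

test_that("X is tolerated and scores zero against anything", {
  a <- global_align("MXK", "MCK")
  expect_equal(a$length, 3)
  b62 <- orthoconj:::blosum62_matrix()
  expect_equal(a$score, b62["M", "M"] + 0 + b62["K", "K"])
})

test_that("scores equal the exhaustive alignment-path oracle for short sequences", {
  set.seed(5)
  sub <- orthoconj:::blosum62_matrix()
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:60) {
    a <- paste(sample(aas, sample(1:5, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:5, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b, sub),
                 info = paste(a, b))
  }
})

test_that("alignment is symmetric in score and identity", {
  set.seed(9)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:20) {
    a <- paste(sample(aas, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:12, 1), TRUE), collapse = "")
    x <- global_align(a, b); y <- global_align(b, a)
    expect_equal(x$score, y$score)
    expect_equal(percent_identity(x), percent_identity(y))
  }
})

test_that("scores agree with an independent alignment engine", {
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  b62 <- orthoconj:::blosum62_matrix()
  for (rep in 1:25) {
    a <- paste(sample(aas, sample(5:60, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(5:60, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      type = "global")
    expect_equal(global_align(a, b)$score, Biostrings::score(ref))
  }
})

test_that("identity counts gap columns in the denominator", {
  aln <- structure(list(aligned_a = paste0(strrep("A", 94), strrep("-", 6)),
                        aligned_b = paste0(strrep("A", 94), strrep("C", 6)),
                        score = 0, matches = 94, length = 100),
                   class = "alignment_result")
  expect_equal(percent_identity(aln), 0.94)
})

test_that("ungapping aligned strings recovers the inputs", {
  set.seed(3)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    a <- paste(sample(aas, sample(2:20, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:20, 1), TRUE), collapse = "")
    x <- global_align(a, b)
    expect_equal(gsub("-", "", x$aligned_a), a)
    expect_equal(gsub("-", "", x$aligned_b), b)
    expect_equal(nchar(x$aligned_a), nchar(x$aligned_b))
  }
})

test_that("identical coding sequences give zero divergence with flagged ratio", {
  d <- estimate_divergence("GGGTTTAAA", "GGGTTTAAA")
  expect_equal(d$dN, 0)
  expect_equal(d$dS, 0)
  expect_true(is.na(d$dn_ds))
})

test_that("a single synonymous third-position change gives dN = 0, dS > 0", {
  a <- paste(c(rep("GGG", 9), "TTT"), collapse = "")
  b <- paste(c(rep("GGG", 9), "TTC"), collapse = "")
  d <- estimate_divergence(a, b)
  expect_equal(d$dN, 0)
  expect_gt(d$dS, 0)
  # hand-counted: S = 9 x 1 + 1/3, Sd = 1, Jukes-Cantor on pS = 3/28
  expect_equal(d$S, 9 + 1/3)
  expect_equal(d$Sd, 1)
  expect_equal(d$dS, -0.75 * log(1 - 4 * (1 / (9 + 1/3)) / 3), tolerance = 1e-12)
  expect_false(d$ds_unreliable)
})

test_that("a single nonsynonymous change gives dS = 0 and a flagged ratio", {
  a <- paste(c(rep("GGG", 9), "AAA"), collapse = "")
  b <- paste(c(rep("GGG", 9), "GAA"), collapse = "")  # K -> E
  d <- estimate_divergence(a, b)
  expect_equal(d$dS, 0)
  expect_gt(d$dN, 0)
  expect_true(is.na(d$dn_ds))
})

test_that("pathway averaging splits a two-position codon difference", {
  # TTT (F) vs TTA (L) differs at one position: nonsynonymous
  # GGA vs AGG differs at positions 1 and 3: paths GGA->AGA->AGG (R,R: one
  # nonsyn then syn) and GGA->GGG->AGG (syn then nonsyn): Sd = Nd = 1
  d <- estimate_divergence(paste(c(rep("CCC", 8), "GGA"), collapse = ""),
                           paste(c(rep("CCC", 8), "AGG"), collapse = ""))
  expect_equal(d$Sd, 1)
  expect_equal(d$Nd, 1)
})

test_that("length mismatches and internal stops are hard errors", {
  expect_error(estimate_divergence("GGGA", "GGG"), "multiple of 3")
  expect_error(estimate_divergence("GGGTTT", "GGG"), "equal length")
  expect_error(estimate_divergence("TAAGGG", "GGGGGG"), "stop")
  # trailing stop codons are tolerated
  d <- estimate_divergence("GGGTAA", "GGGTAA")
  expect_equal(d$dS, 0)
})

test_that("dS saturation is flagged as unreliable", {
  # force a high synonymous proportion with many third-position changes
  a <- paste(rep("GGG", 6), collapse = "")
  b <- paste(rep("GGA", 6), collapse = "")
  d <- estimate_divergence(a, b)
  expect_true(d$ds_unreliable)
  expect_true(is.na(d$dS))
})

test_that("codon alignment excludes gapped codons via the protein alignment", {
  aln <- global_align("MK", "MKR")
  d <- estimate_divergence("ATGAAA", "ATGAAACGT", aln)
  expect_equal(d$S + d$N, 6)  # two comparable codons
  expect_equal(d$dN, 0)
  expect_equal(d$dS, 0)
})

test_that("align_pairs fills identity and divergence columns by pair", {
  prot <- c(g1 = "MKTAY", g2 = "MKTAY", g3 = "MRTAY")
  cds <- c(g1 = "ATGAAAACCGCTTAT", g2 = "ATGAAAACCGCTTAT", g3 = "ATGCGTACCGCTTAT")
  pairs <- data.frame(gene_a = c("g1", "g1", "g1"), gene_b = c("g2", "g3", "gX"),
                      stringsAsFactors = FALSE)
  out <- align_pairs(pairs, prot, cds)
  expect_equal(out$identity[1], 1.0)
  expect_equal(out$identity[2], 0.8)
  expect_true(is.na(out$identity[3]))
  expect_equal(out$dS[1], 0)
  expect_gt(out$dN[2], 0)
})
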