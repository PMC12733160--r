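# RSCU, ENC, expected ENC, positional GC, PR2 and the neutrality regression.

test_that("codon counts tally exactly, stops apart, ambiguity skipped", {
  cc <- codon_counts("ATGTAA")
  expect_equal(cc$counts[["ATG"]], 1L)
  expect_equal(sum(cc$counts), 1L)
  expect_equal(cc$stops, 1L)
  cc2 <- codon_counts(strrep("GCT", 100))
  expect_equal(cc2$counts[["GCT"]], 100L)
  expect_equal(sum(cc2$counts), 100L)
  cc3 <- codon_counts("GCTANTGCC")
  expect_equal(cc3$skipped, 1L)
  expect_equal(sum(cc3$counts), 2L)
  # additivity: counts over genes sum to counts on the concatenation
  g1 <- "ATGGCTTTA"; g2 <- "ATGCCGGAA"
  expect_equal(codon_counts(g1)$counts + codon_counts(g2)$counts,
               codon_counts(paste0(g1, g2))$counts)
})

test_that("RSCU is 1 under equal usage and n under single-codon family usage", {
  code <- plastevo:::genetic_code_11()
  sense <- names(code)[code != "*"]
  r <- rscu(codon_counts(paste(rep(sense, 3), collapse = ""))$counts)
  expect_true(all(abs(r - 1) < 1e-12))
  # all leucine on TTA -> RSCU 6, others 0
  r2 <- rscu(codon_counts(strrep("TTA", 10))$counts)
  expect_equal(r2[["TTA"]], 6)
  expect_equal(unname(r2[c("CTT", "CTC", "CTA", "CTG", "TTG")]), rep(0, 5))
})

test_that("RSCU family means equal 1 for every observed family", {
  set.seed(21)
  fam <- plastevo:::codon_families()
  for (rep_i in 1:20) {
    cds <- random_sense_cds(150)
    r <- rscu(codon_counts(cds)$counts)
    for (aa in names(fam)) {
      cods <- fam[[aa]]
      if (length(cods) < 2 || all(is.na(r[cods]))) next
      expect_equal(mean(r[cods]), 1, tolerance = 1e-12)
    }
  }
})

test_that("ENC reaches its limits and matches direct evaluation on a toy gene", {
  fam <- plastevo:::codon_families()
  one_per_family <- vapply(fam, `[[`, "", 1)
  enc20 <- enc(codon_counts(strrep(paste(one_per_family, collapse = ""), 10))$counts)
  expect_equal(enc20, 20)
  code <- plastevo:::genetic_code_11()
  sense <- names(code)[code != "*"]
  enc61 <- enc(codon_counts(strrep(paste(sense, collapse = ""), 100))$counts)
  expect_equal(enc61, 61)                 # uncapped estimator exceeds 61 slightly
  # hand-specified family counts, evaluated independently:
  # Phe TTT:3 TTC:1  -> F2 = (4*0.625-1)/3  = 0.5
  # Ile ATT:2 ATC:2  -> F3 = (4*0.5-1)/3    = 1/3
  # Ala GCT:2 GCA:2  -> F4 = (4*0.5-1)/3    = 1/3
  # Leu TTA:3 CTT:3  -> F6 = (6*0.5-1)/5    = 0.4
  # ENC = 2 + 9/0.5 + 3 + 15 + 3/0.4 = 45.5
  cds <- paste(c(rep("TTT", 3), "TTC", rep("ATT", 2), rep("ATC", 2),
                 rep("GCT", 2), rep("GCA", 2), rep("TTA", 3), rep("CTT", 3)),
               collapse = "")
  expect_equal(enc(codon_counts(cds)$counts), 45.5, tolerance = 1e-12)
})

test_that("ENC is scale-free in the large-count limit and bounded", {
  set.seed(8)
  code <- plastevo:::genetic_code_11()
  sense <- names(code)[code != "*"]
  for (i in 1:10) {
    # large-count regime: the finite-sample correction in the homozygosity
    # estimator must be negligible before scale invariance can hold
    counts <- setNames(rep(0L, 64), all_codons())
    counts[sense] <- 500L + rpois(length(sense), 1500)
    e1 <- enc(counts)
    e10 <- enc(counts * 10L)
    expect_true(e1 >= 20 && e1 <= 61)
    expect_lt(abs(e1 - e10), 0.1)
    # bounds also hold in the small-count regime
    es <- enc(codon_counts(random_sense_cds(100))$counts)
    expect_true(es >= 20 && es <= 61)
  }
})

test_that("threefold-family imputation follows Wright's fallback", {
  # Phe and Ala observed, Ile absent: F3 imputed as (F2+F4)/2
  cds <- paste(c(rep("TTT", 2), rep("TTC", 2), rep("GCT", 2), rep("GCA", 2),
                 rep("TTA", 2), rep("TTG", 2)), collapse = "")
  counts <- codon_counts(cds)$counts
  f2 <- (4 * 0.5 - 1) / 3; f4 <- f2; f6 <- (4 * 0.5 - 1) / 3
  f3 <- (f2 + f4) / 2
  expect_equal(enc(counts), min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61),
               tolerance = 1e-12)
})

test_that("expected ENC matches the closed form and its symmetry", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  s <- seq(0, 1, by = 0.05)
  expect_equal(expected_enc(s) - s, rev(expected_enc(1 - s) - (1 - s)))
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
})

test_that("positional GC handles limits and exclusion rules", {
  g <- positional_gc("GGGGGGGGG")
  expect_equal(c(g$gc1, g$gc2, g$gc3, g$gc3s), rep(1, 4))
  m <- positional_gc("ATGATGATG")        # Met-only: no synonymous third sites
  expect_true(is.na(m$gc3s))
  expect_equal(m$gc3, 1)                  # all third positions are G
  expect_false(is.na(m$flag))
  # gc12 is the mean of gc1 and gc2
  x <- positional_gc(random_sense_cds(50, seed = 4))
  expect_equal(x$gc12, (x$gc1 + x$gc2) / 2)
})

test_that("PR2 indices hit equilibrium and transform under base swap", {
  b <- pr2_indices("GCAGCTGCGGCC")       # Ala third positions A,T,G,C
  expect_equal(c(b$a3_ratio, b$g3_ratio), c(0.5, 0.5))
  d <- pr2_indices(paste(c(rep("GCA", 3), "GCT", rep("GCG", 2), rep("GCC", 2)),
                         collapse = ""))
  expect_equal(d$a3_ratio, 0.75)
  expect_equal(d$g3_ratio, 0.5)
  # swapping A<->T and G<->C third-position counts maps (x, y) -> (1-x, 1-y);
  # exercised on fourfold-degenerate blocks, where the swap is a within-family
  # permutation of codons
  set.seed(31)
  fam <- plastevo:::codon_families()
  four <- unlist(fam[vapply(fam, length, integer(1)) == 4], use.names = FALSE)
  for (i in 1:10) {
    counts <- setNames(rep(0L, 64), all_codons())
    counts[four] <- sample(0:20, length(four), replace = TRUE)
    swapped <- counts
    swap_names <- paste0(substr(four, 1, 2),
                         chartr("ACGT", "TGCA", substr(four, 3, 3)))
    swapped[swap_names] <- counts[four]
    p <- pr2_indices(counts)
    q <- pr2_indices(swapped)
    expect_equal(q$a3_ratio, 1 - p$a3_ratio, tolerance = 1e-12)
    expect_equal(q$g3_ratio, 1 - p$g3_ratio, tolerance = 1e-12)
  }
})

test_that("neutrality regression matches lm on random inputs and flags degeneracy", {
  set.seed(12)
  for (i in 1:25) {
    gc3 <- runif(10, 0.2, 0.4)
    gc12 <- 0.3 + 0.4 * gc3 + rnorm(10, 0, 0.02)
    fit <- neutrality_fit(gc12, gc3)
    ref <- lm(gc12 ~ gc3)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  }
  ident <- neutrality_fit(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(ident$slope, 1)
  expect_equal(ident$r_squared, 1)
  flat <- neutrality_fit(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  degenerate <- neutrality_fit(c(0.1, 0.2), c(0.3, 0.3))
  expect_true(is.na(degenerate$slope))
  expect_equal(degenerate$flag, "zero variance in GC3")
})
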