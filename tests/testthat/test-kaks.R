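# Codon alignment, NG86 estimation and selection-category statistics.

test_that("identical sequences align gap-free and one deletion is trimmed", {
  a <- gene_sequence("s1", "g", "ATGGCTTTAGAAACTTGGTAA")
  b <- gene_sequence("s2", "g", "ATGGCTTTAGAAACTTGGTAA")
  al <- codon_align(a, b)
  expect_equal(al$codons_a, al$codons_b)
  expect_equal(length(al$codons_a), 6L)   # terminal stop stripped
  # delete one codon from b: that column is trimmed, the rest identical
  b2 <- gene_sequence("s2", "g", "ATGGCTGAAACTTGGTAA")
  al2 <- codon_align(a, b2)
  expect_equal(length(al2$codons_a), 5L)
  expect_equal(al2$codons_a, al2$codons_b)
  expect_error(codon_align(a, gene_sequence("s2", "other", "ATGTAA")),
               "gene names differ")
})

test_that("alignment score is optimal against exhaustive enumeration", {
  set.seed(51)
  aas <- c("A", "R", "N", "D", "C", "G", "L", "K")
  for (i in 1:15) {
    a <- paste(sample(aas, sample(3:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:6, 1), replace = TRUE), collapse = "")
    ia <- match(strsplit(a, "")[[1]], plastevo:::AA_ALPHABET)
    ib <- match(strsplit(b, "")[[1]], plastevo:::AA_ALPHABET)
    got <- plastevo:::nw_align_cpp(ia, ib, 1, -1, 5, 1)$score
    expect_equal(got, align_oracle_score(a, b), tolerance = 1e-9)
  }
})

test_that("NG86 sites are conserved (S + N = 3L) and the estimate is symmetric", {
  set.seed(52)
  for (i in 1:20) {
    ca <- random_sense_cds(60)
    cb <- random_sense_cds(60)
    a <- gene_sequence("s1", "g", ca); b <- gene_sequence("s2", "g", cb)
    kp <- ng86(codon_align(a, b))
    expect_equal(kp$S + kp$N, 3 * kp$n_codons, tolerance = 1e-9)
    kp_rev <- ng86(codon_align(b, a))
    expect_equal(kp$ka, kp_rev$ka, tolerance = 1e-12)
    expect_equal(kp$ks, kp_rev$ks, tolerance = 1e-12)
  }
})

test_that("identical sequences give Ka = Ks = 0 with an undefined ratio", {
  a <- gene_sequence("s1", "g", "ATGGCTTTAGAAACTTGG")
  kp <- ng86(codon_align(a, gene_sequence("s2", "g", a$cds)))
  expect_equal(kp$ka, 0)
  expect_equal(kp$ks, 0)
  expect_true(is.na(kp$ratio))
  expect_equal(kp$category, "undefined")
})

test_that("a single synonymous difference matches the hand-derived JC value", {
  # 11 Ala codons; third positions fully synonymous: S = 11, N = 22
  a <- gene_sequence("s1", "g", paste0(strrep("GCT", 10), "GCA"))
  b <- gene_sequence("s2", "g", paste0(strrep("GCT", 10), "GCG"))
  kp <- ng86(codon_align(a, b))
  expect_equal(kp$S, 11)
  expect_equal(kp$N, 22)
  expect_equal(kp$ka, 0)
  expect_equal(kp$ks, -0.75 * log(1 - 4 * (1 / 11) / 3), tolerance = 1e-12)
  expect_equal(kp$ratio, 0)
})

test_that("two-difference codons average over both substitution orders", {
  # single codon pair AAA (Lys) vs AGG (Arg): pathways
  #   AAA->AGA(N)->AGG(S)  and  AAA->AAG(S)->AGG(N)
  # averaged: Sd = 1, Nd = 1
  tab <- plastevo:::ng86_tables()
  expect_equal(tab$sd["AAA", "AGG"], 1)
  expect_equal(tab$nd["AAA", "AGG"], 1)
  # pathway through a stop is excluded: TTA (Leu) vs TAT (Tyr)
  #   TTA->TAA is a stop; only TTA->TTT(N)->TAT(N) remains
  expect_equal(tab$sd["TTA", "TAT"], 0)
  expect_equal(tab$nd["TTA", "TAT"], 2)
  # brute-force pathway oracle over all two-difference sense pairs
  code <- plastevo:::genetic_code_11()
  sense <- names(code)[code != "*"]
  set.seed(53)
  pick <- sample(sense, 12)
  for (c1 in pick) {
    for (c2 in pick) {
      s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
      dp <- which(s1 != s2)
      if (length(dp) != 2) next
      ords <- list(dp, rev(dp))
      tots <- c(0, 0); legal <- 0
      for (o in ords) {
        cur <- s1; sd_ <- 0; nd_ <- 0; ok <- TRUE
        for (pos in o) {
          nxt <- cur; nxt[pos] <- s2[pos]
          from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
          if (code[[to]] == "*") { ok <- FALSE; break }
          if (code[[from]] == code[[to]]) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
          cur <- nxt
        }
        if (ok) { tots <- tots + c(sd_, nd_); legal <- legal + 1 }
      }
      if (legal > 0) {
        expect_equal(tab$sd[c1, c2], tots[1] / legal)
        expect_equal(tab$nd[c1, c2], tots[2] / legal)
      } else {
        expect_true(is.na(tab$sd[c1, c2]))
      }
    }
  }
})

test_that("selection categories follow the Ka/Ks thresholds", {
  mk <- function(r) data.frame(gene = "g", species_a = "a", species_b = "b",
                               category = "other", ka = r, ks = 1, ratio = r,
                               selection = ifelse(r < 0.5, "strong purifying",
                                                  ifelse(r <= 1, "relaxed purifying",
                                                         "positive")))
  pairs <- do.call(rbind, lapply(c(0.3, 0.3, 0.7, 1.2), mk))
  ss <- selection_summary(pairs)
  expect_equal(unname(ss$class_fractions),
               c(0.5, 0.25, 0.25))
  # outlier rule: ratio > 10 removed before summaries
  pairs2 <- rbind(pairs, mk(50))
  ss2 <- selection_summary(pairs2)
  expect_equal(ss2$outliers_removed, 1L)
  expect_equal(ss2$n_pairs_defined, 4L)
})

test_that("degenerate one-category input yields zero effect size", {
  pairs <- data.frame(gene = "g", species_a = "a", species_b = letters[1:6],
                      category = rep(c("catA", "catB"), each = 3),
                      ka = 0.3, ks = 1, ratio = 0.3,
                      selection = "strong purifying")
  ss <- selection_summary(pairs)
  expect_equal(unname(ss$class_fractions[["strong purifying"]]), 1)
  expect_equal(ss$pairwise_tests$cohens_d, 0)
  expect_equal(ss$pairwise_tests$mean_diff, 0)
})

test_that("simulated orthologs at increasing omega give increasing Ka/Ks", {
  tr <- ape::read.tree(text = "(A:0.08,B:0.08);")
  set.seed(59)
  means <- vapply(c(0.1, 0.5, 1.0), function(om) {
    anc <- lapply(1:200, function(i)
      gene_sequence("anc", paste0("g", i), random_sense_cds(120)))
    ev <- evolve_orthologs(anc, tr, omega = om, mutation_rate = 1,
                           seed = 60 + round(100 * om))
    pr <- kaks_pairs(c(ev$leaf_genes$A, ev$leaf_genes$B))
    mean(pr$ratio, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[1] - 0.1), 0.05)
})
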