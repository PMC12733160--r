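# GenBank/FASTA parsing, quadripartite detection, CDS curation, region
# statistics and gene-order synteny.

test_that("minimal GenBank file with a two-exon CDS parses with intron derived", {
  gb <- c(
    "LOCUS       toy 60 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             join(4..9,16..21)",
    '                     /gene="demo"',
    "ORIGIN",
    "        1 aaaatggcaa aaaaagcgta aaaaaaaaaa aaaaaaaaaa aaaaaaaaaa aaaaaaaaaa",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- parse_plastome(path)
  expect_equal(length(rec$genes), 1L)
  expect_equal(nrow(rec$genes[[1]]$exons), 2L)
  expect_equal(rec$genes[[1]]$exons[1, ], c(start = 3L, end = 9L))
  expect_equal(nrow(plastevo:::gene_introns(rec$genes[[1]])), 1L)
})

test_that("FASTA without annotation yields an empty gene list", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp1", "ACGTACGTACGT"), path)
  rec <- parse_plastome(path)
  expect_equal(rec$species_id, "sp1")
  expect_equal(length(rec$genes), 0L)
})

test_that("unknown feature classes are ignored with a warning", {
  gb <- c(
    "LOCUS       toy 12 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     misc_feature    1..4",
    '                     /note="x"',
    "ORIGIN",
    "        1 acgtacgtacgt",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_warning(rec <- read_genbank(path), "unknown class")
  expect_equal(length(rec$genes), 0L)
})

test_that("write/parse round trip is the identity on the canonical serialization", {
  sim <- simulate_plastome(small_sim_config(11), species_id = "rt")
  p1 <- withr::local_tempfile(fileext = ".gb")
  p2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$record, p1)
  rec2 <- parse_plastome(p1)
  write_genbank(rec2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(rec2$sequence, sim$record$sequence)
  expect_equal(length(rec2$genes), length(sim$record$genes))
  # FASTA + annotation TSV route reproduces the same record
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_plastome_fasta(sim$record, fa)
  rec3 <- parse_plastome(fa)
  expect_identical(rec3$sequence, sim$record$sequence)
  expect_equal(vapply(rec3$genes, `[[`, "", "name"),
               vapply(sim$record$genes, `[[`, "", "name"))
})

test_that("planted toy inverted repeat is recovered with correct region labels", {
  set.seed(5)
  ir <- random_dna(100)
  # period-insulated construction: flank segments drawn independently
  s <- paste0(random_dna(700), ir, random_dna(100), revcomp(ir))
  rec <- plastome_record("toy", s)
  b <- detect_quadripartite(rec, min_ir = 60)
  rl <- region_lengths(b, nchar(s))
  expect_gte(rl[["ira"]], 100)            # >= planted (chance extension possible)
  expect_equal(rl[["ira"]], rl[["irb"]])
  expect_gte(rl[["lsc"]], rl[["ssc"]])
  expect_equal(sum(rl), nchar(s))
  # IR symmetry: IRa reverse complement equals IRb byte-for-byte
  ira_seq <- plastevo:::circ_substr(s, b$ira[1], b$ira[2])
  irb_seq <- plastevo:::circ_substr(s, b$irb[1], b$irb[2])
  expect_identical(revcomp(ira_seq), irb_seq)
})

test_that("synthetic plastome boundaries are recovered exactly and invariantly", {
  sim <- simulate_plastome(small_sim_config(3), species_id = "inv")
  rec <- sim$record
  n <- nchar(rec$sequence)
  b <- detect_quadripartite(rec, min_ir = 500)
  expect_equal(unname(region_lengths(b, n)[c("lsc", "ssc", "ira")]),
               unname(sim$truth$region_lengths[c("lsc", "ssc", "ir")]))
  expect_equal(sum(region_lengths(b, n)), n)
  # rotation invariance
  rot <- paste0(substr(rec$sequence, 5001, n), substr(rec$sequence, 1, 5000))
  b_rot <- detect_quadripartite(plastome_record("rot", rot), min_ir = 500)
  expect_equal(sort(region_lengths(b_rot, n)), sort(region_lengths(b, n)))
  # reverse-complement invariance
  b_rc <- detect_quadripartite(plastome_record("rc", revcomp(rec$sequence)),
                               min_ir = 500)
  expect_equal(sort(region_lengths(b_rc, n)), sort(region_lengths(b, n)))
})

test_that("genomes without a long inverted repeat raise the structure error", {
  set.seed(9)
  rec <- plastome_record("noir", random_dna(2000))
  expect_error(detect_quadripartite(rec, min_ir = 300), "no quadripartite")
})

test_that("CDS curation filters reject frame and internal-stop violations", {
  seqs <- paste0(
    "ATGGCTGCA",               # good, + strand
    "A",                        # spacer breaks frame bookkeeping
    "TTACAT",                   # minus strand: revcomp = ATGTAA
    "ATGGCTA",                  # length 7: not multiple of 3
    "ATGTAAGCTGCA")             # internal stop at codon 2
  rec <- plastome_record("flt", seqs, list(
    gene_annotation("goodA", "CDS", "+", cbind(0, 9)),
    gene_annotation("minusB", "CDS", "-", cbind(10, 16)),
    gene_annotation("badFrame", "CDS", "+", cbind(16, 23)),
    gene_annotation("badStop", "CDS", "+", cbind(23, 35))))
  ext <- extract_cds(rec)
  kept <- vapply(ext$genes, `[[`, "", "gene_name")
  expect_setequal(kept, c("goodA", "minusB"))
  expect_equal(ext$genes[[which(kept == "minusB")]]$cds, "ATGTAA")
  expect_equal(ext$rejected$reason[ext$rejected$gene == "badFrame"],
               "length not multiple of 3")
  expect_equal(ext$rejected$reason[ext$rejected$gene == "badStop"],
               "internal stop")
})

test_that("inverted-repeat gene duplicates collapse to the lower-start copy", {
  cds <- "ATGGCTGCATAA"
  s <- paste0(cds, strrep("A", 20), cds)
  rec <- plastome_record("dup", s, list(
    gene_annotation("psbA", "CDS", "+", cbind(0, 12)),
    gene_annotation("psbA", "CDS", "+", cbind(32, 44))))
  ext <- extract_cds(rec)
  expect_equal(length(ext$genes), 1L)
})

test_that("region statistics report composition and codon-position GC", {
  rec <- plastome_record("at", strrep("AT", 50))
  st <- region_stats(rec)
  expect_equal(st$gc_pct, 0)
  # fixed composition: 10 kb with 1869 C, 1822 G
  s <- paste0(strrep("C", 1869), strrep("G", 1822), strrep("A", 3115),
              strrep("T", 3194))
  st2 <- region_stats(plastome_record("gc", s))
  expect_equal(st2$gc_pct, 36.91)
  expect_equal(st2$composition_pct[["C"]], 18.69)
  expect_equal(st2$composition_pct[["G"]], 18.22)
})

test_that("gene counts tally by feature class", {
  genes <- c(
    lapply(1:7, function(i) gene_annotation(paste0("cds", i), "CDS", "+",
                                            cbind(10 * i, 10 * i + 6))),
    lapply(1:3, function(i) gene_annotation(paste0("trn", i), "tRNA", "+",
                                            cbind(100 + 10 * i, 105 + 10 * i))),
    list(gene_annotation("rrn16", "rRNA", "+", cbind(200, 250))))
  rec <- plastome_record("cnt", random_dna(300), genes)
  st <- region_stats(rec)
  expect_equal(unname(st$gene_counts), c(7L, 3L, 1L))
  expect_equal(st$n_genes, 11L)
})

test_that("synteny of identical, inverted and disjoint gene orders", {
  mk <- function(names, strands = rep("+", length(names))) {
    genes <- lapply(seq_along(names), function(i)
      gene_annotation(names[i], "CDS", strands[i], cbind(20 * i, 20 * i + 9)))
    plastome_record(paste(names, collapse = ""), random_dna(20 * length(names) + 20),
                    genes)
  }
  nm <- paste0("g", 1:10)
  a <- mk(nm)
  sy_id <- gene_order_synteny(a, mk(nm))
  expect_equal(sy_id$n_blocks, 1L)
  expect_equal(sy_id$breakpoints, 0L)
  expect_equal(sy_id$collinear_fraction, 1)
  # one internal segment (4..6) inverted: 3 blocks, 2 breakpoints
  inv <- c(nm[1:3], rev(nm[4:6]), nm[7:10])
  strands <- c(rep("+", 3), rep("-", 3), rep("+", 4))
  sy_inv <- gene_order_synteny(a, mk(inv, strands))
  expect_equal(sy_inv$n_blocks, 3L)
  expect_equal(sy_inv$breakpoints, 2L)
  expect_error(gene_order_synteny(a, mk(paste0("h", 1:5))),
               "insufficient shared annotation")
})
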