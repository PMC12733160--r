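# Synthetic plastome generator.  Produces circular quadripartite genomes
# (IRb the exact reverse complement of IRa by construction), AT-biased
# protein-coding genes, planted perfect SSRs with exact truth coordinates,
# and orthologous gene sets diverged under a controllable Ka/Ks ratio.
# All randomness is driven by the config seed.

#' Simulation configuration
#'
#' Defaults mirror a strongly IR-expanded, SSC-contracted epidendroid
#' plastome: LSC 85,994 bp, SSC 608 bp, IR 37,024 bp (160,650 bp total),
#' AT-rich composition (intergenic AT ~ 0.65, target GC3 ~ 0.27).
#'
#' @param seed integer seed fixing all randomness
#' @param lsc_len,ssc_len,ir_len region lengths in bp
#' @param n_genes_lsc,n_genes_ssc,n_genes_ir CDS genes per region (the IR
#'   genes are duplicated in both copies)
#' @param target_gc3 target GC fraction at third codon positions
#' @param intergenic_at AT fraction of intergenic filler
#' @param ssr_plan data frame with columns motif, copies, region
#'   (`"lsc"`/`"ssc"`/`"ir"`); NULL plants a default mixed plan; use a
#'   0-row data frame for none
#' @param gene_len_range codon-count range for simulated CDSs
#' @return list of class `sim_config`
#' @export
simulation_config <- function(seed = 1L,
                              lsc_len = 85994L, ssc_len = 608L, ir_len = 37024L,
                              n_genes_lsc = 40L, n_genes_ssc = 0L, n_genes_ir = 6L,
                              target_gc3 = 0.27, intergenic_at = 0.65,
                              ssr_plan = NULL, gene_len_range = c(120L, 360L)) {
  if (any(c(lsc_len, ssc_len, ir_len) <= 0)) stop("region lengths must be positive")
  if (lsc_len < ssc_len) stop("LSC must be at least as long as SSC")
  if (is.null(ssr_plan))
    ssr_plan <- data.frame(
      motif = c("A", "T", "AT", "TTG", "ATCG", "ATTTGTACA"),
      copies = c(12L, 11L, 7L, 6L, 5L, 3L),
      region = c("lsc", "lsc", "lsc", "ssc", "lsc", "lsc"),
      stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
                 n_genes_lsc = n_genes_lsc, n_genes_ssc = n_genes_ssc,
                 n_genes_ir = n_genes_ir, target_gc3 = target_gc3,
                 intergenic_at = intergenic_at, ssr_plan = ssr_plan,
                 gene_len_range = gene_len_range),
            class = "sim_config")
}

# AT-biased random nucleotide string
random_filler <- function(n, at_frac) {
  if (n == 0) return("")
  p <- c(A = at_frac / 2, C = (1 - at_frac) / 2,
         G = (1 - at_frac) / 2, T = at_frac / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# sample one in-frame CDS: ATG + sense codons biased to the target GC3 + stop
random_cds <- function(n_codons, target_gc3) {
  fam <- codon_families()
  code <- genetic_code_11()
  sense <- names(code)[code != "*"]
  third_gc <- substr(sense, 3, 3) %in% c("G", "C")
  w <- ifelse(third_gc, target_gc3, 1 - target_gc3)
  # mild AT bias at positions 1-2 as well
  w <- w * (1 - 0.3 * (substr(sense, 1, 1) %in% c("G", "C"))) *
    (1 - 0.3 * (substr(sense, 2, 2) %in% c("G", "C")))
  body <- sample(sense, n_codons - 2, replace = TRUE, prob = w)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1, prob = c(0.6, 0.2, 0.2))
  paste0("ATG", paste(body, collapse = ""), stop_codon)
}

# plastid-style gene name pools used for synthetic annotations
sim_gene_pool <- function() {
  c("psbA", "psbB", "psbC", "psbD", "psbE", "psbK", "psaA", "psaB", "psaC",
    "petA", "petB", "petD", "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
    "rbcL", "rpoA", "rpoB", "rpoC1", "rpoC2", "rps2", "rps3", "rps4", "rps7",
    "rps8", "rps11", "rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "ndhA",
    "ndhB", "ndhC", "ndhD", "ndhE", "matK", "ccsA", "cemA", "clpP", "accD",
    "ycf1", "ycf2", "ycf3", "ycf4", "infA", "psbF", "psbH", "psbI", "psbJ",
    "psbL", "psbM", "psbN", "psbT", "psbZ", "rps12", "rps14", "rps15",
    "rps16", "rps18", "rps19", "rpl23", "rpl32", "rpl33", "rpl36", "ndhF",
    "ndhG", "ndhH", "ndhI", "ndhJ", "ndhK")
}

#' Simulate one quadripartite plastome with ground truth
#'
#' The circle is assembled as LSC, IRb, SSC, IRa with IRb equal to the
#' reverse complement of IRa by construction.  Genes are placed without
#' overlap at evenly spread positions, intergenic filler is AT-rich, and
#' SSRs from the plan are planted in intergenic space with
#' period-breaking flanks so their coordinates are exact.
#'
#' @param config a [simulation_config()]
#' @param species_id identifier for the record
#' @return list with `record` (a [plastome_record()]), `truth` (list with
#'   `boundaries`, `region_lengths`, `genes` and `ssrs` data frames)
#' @export
simulate_plastome <- function(config, species_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pool <- sim_gene_pool()
  total <- config$lsc_len + config$ssc_len + 2L * config$ir_len
  offsets <- c(lsc = 0L, irb = config$lsc_len,
               ssc = config$lsc_len + config$ir_len,
               ira = config$lsc_len + config$ir_len + config$ssc_len)

  build_region <- function(len, n_genes, gene_names, plan) {
    chars <- strsplit(random_filler(len, config$intergenic_at), "")[[1]]
    occupied <- rep(FALSE, len)
    genes <- list()
    if (n_genes > 0) {
      cds_list <- lapply(seq_len(n_genes), function(i)
        random_cds(sample(seq(config$gene_len_range[1], config$gene_len_range[2]), 1),
                   config$target_gc3))
      need <- sum(nchar(unlist(cds_list)))
      if (need + sum(nchar(plan$motif) * plan$copies + 4) >= len)
        stop("gene/SSR plan exceeds region capacity (", need, " bp of CDS in ",
             len, " bp)")
      gap <- floor((len - need) / (n_genes + 1))
      pos <- 1L
      for (i in seq_len(n_genes)) {
        pos <- pos + gap
        cds <- cds_list[[i]]
        w <- nchar(cds)
        strand <- if (i %% 3 == 0) "-" else "+"
        placed <- if (strand == "-") revcomp(cds) else cds
        chars[pos:(pos + w - 1)] <- strsplit(placed, "")[[1]]
        occupied[pos:(pos + w - 1)] <- TRUE
        genes[[i]] <- list(name = gene_names[i], strand = strand,
                           start = pos - 1L, end = pos - 1L + w)
        pos <- pos + w
      }
    }
    # plant SSRs in free intergenic space, breaking the period at both flanks
    ssrs <- list()
    if (nrow(plan) > 0) {
      free_runs <- function() {
        r <- rle(occupied)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        cbind(starts[!r$values], ends[!r$values])
      }
      for (k in seq_len(nrow(plan))) {
        motif <- toupper(plan$motif[k]); cp <- plan$copies[k]
        w <- nchar(motif) * cp
        runs <- free_runs()
        ok <- runs[, 2] - runs[, 1] + 1 >= w + 4
        if (!any(ok)) stop("SSR plan exceeds region capacity")
        run <- runs[which(ok)[1], ]
        s <- run[1] + 2L
        rep_chars <- strsplit(strrep(motif, cp), "")[[1]]
        chars[s:(s + w - 1)] <- rep_chars
        # period-breaking flanks so the planted run is maximal and exact
        brk <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
        chars[s - 1] <- brk(substr(motif, nchar(motif), nchar(motif)))
        chars[s + w] <- brk(substr(motif, 1, 1))
        occupied[(s - 1):(s + w)] <- TRUE
        ssrs[[k]] <- list(motif = motif, copies = cp, start = s - 1L,
                          end = s - 1L + w)
      }
    }
    list(seq = paste(chars, collapse = ""), genes = genes, ssrs = ssrs)
  }

  plan <- config$ssr_plan
  reg_plan <- function(rg) plan[plan$region == rg, , drop = FALSE]
  n_total_genes <- config$n_genes_lsc + config$n_genes_ssc + config$n_genes_ir
  if (n_total_genes > length(pool))
    stop("gene plan exceeds the available name pool (", length(pool), ")")
  names_lsc <- pool[seq_len(config$n_genes_lsc)]
  names_ssc <- pool[config$n_genes_lsc + seq_len(config$n_genes_ssc)]
  names_ir <- pool[config$n_genes_lsc + config$n_genes_ssc +
                     seq_len(config$n_genes_ir)]

  lsc <- build_region(config$lsc_len, config$n_genes_lsc, names_lsc, reg_plan("lsc"))
  ssc <- build_region(config$ssc_len, config$n_genes_ssc, names_ssc, reg_plan("ssc"))
  ira <- build_region(config$ir_len, config$n_genes_ir, names_ir, reg_plan("ir"))
  irb_seq <- revcomp(ira$seq)

  sequence <- paste0(lsc$seq, irb_seq, ssc$seq, ira$seq)
  stopifnot(nchar(sequence) == total)

  gene_rows <- list(); annotations <- list()
  add_gene <- function(name, strand, start, end, region) {
    annotations[[length(annotations) + 1]] <<-
      gene_annotation(name, "CDS", strand, cbind(start, end))
    gene_rows[[length(gene_rows) + 1]] <<-
      data.frame(name = name, class = "CDS", strand = strand, start = start,
                 end = end, region = region, stringsAsFactors = FALSE)
  }
  for (g in lsc$genes) add_gene(g$name, g$strand, g$start, g$end, "lsc")
  for (g in ssc$genes)
    add_gene(g$name, g$strand, offsets[["ssc"]] + g$start,
             offsets[["ssc"]] + g$end, "ssc")
  for (g in ira$genes) {
    add_gene(g$name, g$strand, offsets[["ira"]] + g$start,
             offsets[["ira"]] + g$end, "ira")
    # mirrored IRb copy: reverse-complemented position and strand
    s2 <- offsets[["irb"]] + (config$ir_len - g$end)
    e2 <- offsets[["irb"]] + (config$ir_len - g$start)
    add_gene(g$name, if (g$strand == "+") "-" else "+", s2, e2, "irb")
  }

  ssr_rows <- list()
  add_ssr <- function(s, region_off, region) {
    ssr_rows[[length(ssr_rows) + 1]] <<-
      data.frame(motif = s$motif, unit_len = nchar(s$motif), copies = s$copies,
                 start = region_off + s$start, end = region_off + s$end,
                 region = region, stringsAsFactors = FALSE)
  }
  for (s in lsc$ssrs) add_ssr(s, 0L, "lsc")
  for (s in ssc$ssrs) add_ssr(s, offsets[["ssc"]], "ssc")
  for (s in ira$ssrs) add_ssr(s, offsets[["ira"]], "ira")

  boundaries <- region_boundaries(
    lsc = c(0L, offsets[["irb"]]),
    irb = c(offsets[["irb"]], offsets[["ssc"]]),
    ssc = c(offsets[["ssc"]], offsets[["ira"]]),
    ira = c(offsets[["ira"]], 0L))
  record <- plastome_record(species_id, sequence, annotations, boundaries)
  truth <- list(
    boundaries = boundaries,
    region_lengths = c(lsc = config$lsc_len, ssc = config$ssc_len,
                       ir = config$ir_len),
    genes = if (length(gene_rows) > 0) do.call(rbind, gene_rows) else NULL,
    ssrs = if (length(ssr_rows) > 0) do.call(rbind, ssr_rows) else NULL)
  list(record = record, truth = truth)
}

#' Evolve orthologous gene copies along a tree
#'
#' Codon-level rejection sampling: along each branch, point mutations are
#' proposed at the branch-length rate (expected proposals per site), proposals
#' creating stop codons are rejected, synonymous proposals are always
#' accepted and nonsynonymous proposals are accepted with probability
#' `omega`.  Realized synonymous/nonsynonymous substitution counts are
#' recorded per branch and gene.
#'
#' @param ancestor_genes list of [gene_sequence()] at the root
#' @param tree `ape::phylo` with branch lengths in expected proposals/site
#' @param omega nonsynonymous acceptance probability (>= 0)
#' @param mutation_rate multiplier on branch lengths
#' @param seed integer seed
#' @return list with `leaf_genes` (named list: tip label -> list of
#'   [gene_sequence()]) and `realized` (data frame of per-branch counts)
#' @export
evolve_orthologs <- function(ancestor_genes, tree, omega = 0.2,
                             mutation_rate = 1, seed = 1L) {
  if (omega < 0) stop("omega must be >= 0")
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  code <- genetic_code_11()
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  realized <- list()

  evolve_one <- function(cds, bl) {
    cod <- codon_vector(cds)
    body <- seq_len(length(cod) - 1L)          # keep the terminal stop fixed
    L <- 3L * length(body)
    n_prop <- rpois(1, L * bl * mutation_rate)
    syn <- 0L; nonsyn <- 0L
    if (n_prop > 0) {
      for (k in seq_len(n_prop)) {
        ci <- sample(body, 1)
        pos <- sample(3L, 1)
        old <- cod[ci]
        base <- substr(old, pos, pos)
        new_base <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
        new <- old
        substr(new, pos, pos) <- new_base
        if (code[[new]] == "*") next           # reject stop-creating proposal
        if (code[[new]] == code[[old]]) {
          cod[ci] <- new; syn <- syn + 1L
        } else if (runif(1) < omega) {
          cod[ci] <- new; nonsyn <- nonsyn + 1L
        }
      }
    }
    list(cds = paste(cod, collapse = ""), syn = syn, nonsyn = nonsyn)
  }

  seqs_at <- vector("list", n_tip + tree$Nnode)
  seqs_at[[root]] <- lapply(ancestor_genes, `[[`, "cds")
  out_genes <- setNames(vector("list", n_tip), tree$tip.label)
  edges <- tree$edge
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    bl <- tree$edge.length[e]
    res <- lapply(seq_along(ancestor_genes), function(gi)
      evolve_one(seqs_at[[parent]][[gi]], bl))
    seqs_at[[child]] <- lapply(res, `[[`, "cds")
    realized[[length(realized) + 1]] <- data.frame(
      parent = parent, child = child,
      gene = vapply(ancestor_genes, `[[`, "", "gene_name"),
      syn = vapply(res, `[[`, integer(1), "syn"),
      nonsyn = vapply(res, `[[`, integer(1), "nonsyn"),
      stringsAsFactors = FALSE)
    if (child <= n_tip) {
      tip <- tree$tip.label[child]
      out_genes[[tip]] <- lapply(seq_along(ancestor_genes), function(gi)
        gene_sequence(tip, ancestor_genes[[gi]]$gene_name,
                      seqs_at[[child]][[gi]],
                      ancestor_genes[[gi]]$category))
    }
  }
  list(leaf_genes = out_genes, realized = do.call(rbind, realized))
}
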