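# Structural operations on one or two plastome records: quadripartite
# boundary detection from exact inverted repeats, CDS extraction with the
# curation filters, per-genome structural statistics and gene-order synteny.

#' Detect the quadripartite LSC/IRb/SSC/IRa structure
#'
#' Finds the maximal-length pair of exact reverse-complement repeats on the
#' circular sequence (searched on the doubled sequence so repeats may span
#' the origin).  The two single-copy gaps between the repeats are labeled
#' LSC (longer) and SSC (shorter), and the genome is reported in the
#' orientation LSC, IRb, SSC, IRa.
#'
#' @param record a [plastome_record()]
#' @param min_ir minimum inverted-repeat length in bp to call a structure
#' @return a [region_boundaries()] object
#' @export
detect_quadripartite <- function(record, min_ir = 1000) {
  res <- longest_ir_cpp(record$sequence, as.integer(min_ir))
  if (res$len == 0 || res$len < min_ir)
    stop("no quadripartite structure: no inverted repeat of length >= ", min_ir)
  n <- nchar(record$sequence)
  L <- res$len
  pairs <- unique(t(apply(cbind(res$pos_a, res$pos_b), 1, sort)))
  if (nrow(pairs) > 1)
    stop("ambiguous inverted repeats: multiple maximal pairs of length ", L,
         " at offsets {", paste(apply(pairs, 1, paste, collapse = ","),
                                collapse = "} {"), "}")
  p <- pairs[1, 1]; q <- pairs[1, 2]
  gap_a <- (q - p - L) %% n                      # between IR at p and IR at q
  gap_b <- (p - q - L) %% n                      # between IR at q and IR at p
  if (gap_b >= gap_a) {
    b <- region_boundaries(lsc = c((q + L) %% n, p), irb = c(p, (p + L) %% n),
                           ssc = c((p + L) %% n, q), ira = c(q, (q + L) %% n))
  } else {
    b <- region_boundaries(lsc = c((p + L) %% n, q), irb = c(q, (q + L) %% n),
                           ssc = c((q + L) %% n, p), ira = c(p, (p + L) %% n))
  }
  stopifnot(sum(region_lengths(b, n)) == n)
  b
}

#' A curated protein-coding gene sequence
#'
#' @param species_id species identifier
#' @param gene_name gene name
#' @param cds spliced, strand-corrected nucleotide sequence (length divisible
#'   by 3, no internal stop under the plastid code)
#' @param category functional category label (see [plastid_gene_category()])
#' @return an object of class `gene_sequence`
#' @export
gene_sequence <- function(species_id, gene_name, cds,
                          category = plastid_gene_category(gene_name)) {
  stopifnot(nchar(cds) %% 3 == 0)
  structure(list(species_id = species_id, gene_name = gene_name,
                 cds = toupper(cds), category = category),
            class = "gene_sequence")
}

#' Extract and curate protein-coding sequences
#'
#' Splices each CDS feature across its exons, reverse-complements
#' minus-strand genes, deduplicates genes annotated twice (inverted-repeat
#' copies, keeping the copy with the lower start coordinate), and applies the
#' curation filters: length a multiple of three and no internal stop codon
#' under the plastid code.  Failing genes are reported, never dropped
#' silently.
#'
#' @param record a [plastome_record()]
#' @return list with `genes` (list of [gene_sequence()]) and `rejected`
#'   (data frame of gene name and reason)
#' @export
extract_cds <- function(record) {
  cds_feats <- Filter(function(g) g$feature_class == "CDS", record$genes)
  if (length(cds_feats) == 0)
    return(list(genes = list(), rejected = data.frame(gene = character(0),
                                                      reason = character(0))))
  starts <- vapply(cds_feats, function(g) min(g$exons[, 1]), numeric(1))
  keys <- tolower(vapply(cds_feats, `[[`, "", "name"))
  # keep the lowest-start copy of each duplicated (inverted-repeat) name
  ord <- order(keys, starts)
  cds_feats <- cds_feats[ord][!duplicated(keys[ord])]
  genes <- list(); rej_gene <- character(0); rej_reason <- character(0)
  for (g in cds_feats) {
    parts <- apply(g$exons, 1, function(iv)
      substr(record$sequence, iv[1] + 1, iv[2]))
    cds <- paste(parts, collapse = "")
    if (g$strand == "-") cds <- revcomp(cds)
    if (nchar(cds) %% 3 != 0) {
      rej_gene <- c(rej_gene, g$name)
      rej_reason <- c(rej_reason, "length not multiple of 3")
      next
    }
    aa <- strsplit(translate_cds(cds), "")[[1]]
    if (length(aa) > 1 && any(aa[-length(aa)] == "*")) {
      rej_gene <- c(rej_gene, g$name)
      rej_reason <- c(rej_reason, "internal stop")
      next
    }
    genes[[length(genes) + 1]] <- gene_sequence(record$species_id, g$name, cds)
  }
  list(genes = genes,
       rejected = data.frame(gene = rej_gene, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

#' Per-genome structural summary
#'
#' @param record a [plastome_record()]
#' @param boundaries optional [region_boundaries()]; taken from the record if
#'   present there
#' @return list with total length, region lengths, base composition (%),
#'   GC%, gene counts by feature class, and GC by codon position over the
#'   concatenated retained CDSs (absent and flagged when no CDS survives)
#' @export
region_stats <- function(record, boundaries = record$boundaries) {
  n <- nchar(record$sequence)
  comp <- table(factor(strsplit(record$sequence, "")[[1]],
                       levels = c("A", "C", "G", "T", "N")))
  comp_pct <- 100 * as.numeric(comp) / n
  names(comp_pct) <- names(comp)
  gc_pct <- comp_pct[["G"]] + comp_pct[["C"]]
  classes <- vapply(record$genes, `[[`, "", "feature_class")
  nm <- vapply(record$genes, `[[`, "", "name")
  counts <- c(CDS = length(unique(tolower(nm[classes == "CDS"]))),
              tRNA = sum(classes == "tRNA"),
              rRNA = sum(classes == "rRNA"))
  out <- list(species_id = record$species_id, length = n,
              composition_pct = comp_pct, gc_pct = gc_pct,
              gene_counts = counts, n_genes = sum(counts))
  if (!is.null(boundaries)) {
    rl <- region_lengths(boundaries, n)
    out$region_lengths <- c(lsc = rl[["lsc"]], ssc = rl[["ssc"]],
                            ir = rl[["ira"]])
  }
  ext <- extract_cds(record)
  if (length(ext$genes) > 0) {
    concat <- paste(vapply(ext$genes, `[[`, "", "cds"), collapse = "")
    pg <- positional_gc_string(concat)
    out$gc_codon_pos <- 100 * c(gc1 = pg$gc1, gc2 = pg$gc2, gc3 = pg$gc3)
  } else {
    out$gc_codon_pos <- NULL
    out$gc_codon_pos_flag <- "no retained CDS"
  }
  out
}

#' Gene-order synteny between two annotated plastomes
#'
#' Restricts both genomes to their shared genes (name comparison is
#' case-insensitive, duplicated annotations collapsed to the lowest-start
#' copy), forms signed gene orders by start coordinate and strand, and
#' summarizes collinearity: maximal signed collinear runs, breakpoint count
#' and the fraction of shared genes lying in runs of length at least two.
#'
#' @param a,b [plastome_record()] objects
#' @return list with `n_shared`, `blocks` (list of gene-name vectors),
#'   `n_blocks`, `breakpoints`, `longest_block`, `collinear_fraction`
#' @export
gene_order_synteny <- function(a, b) {
  ord <- function(rec) {
    nm <- vapply(rec$genes, `[[`, "", "name")
    st <- vapply(rec$genes, function(g) min(g$exons[, 1]), numeric(1))
    sn <- vapply(rec$genes, `[[`, "", "strand")
    key <- tolower(nm)
    o <- order(key, st)
    first <- o[!duplicated(key[o])]
    first <- first[order(st[first])]
    data.frame(name = nm[first], key = key[first], start = st[first],
               strand = sn[first], stringsAsFactors = FALSE)
  }
  oa <- ord(a); ob <- ord(b)
  shared <- intersect(oa$key, ob$key)
  if (length(shared) < 2) stop("insufficient shared annotation")
  oa <- oa[oa$key %in% shared, ]; ob <- ob[ob$key %in% shared, ]
  idx <- match(ob$key, oa$key)                   # position of b's genes in a
  sign_a <- ifelse(oa$strand == "+", 1L, -1L)
  sign_b <- ifelse(ob$strand == "+", 1L, -1L)
  signed <- idx * sign_b * sign_a[idx]           # relative orientation
  m <- length(signed)
  # signed adjacency: a forward run (+k, +k+1) and an inverted run
  # (-k-1, -k) both advance the signed index by exactly one
  adj <- signed[-1] == signed[-m] + 1
  cuts <- c(0, which(!adj), m)
  blocks <- lapply(seq_len(length(cuts) - 1), function(k)
    ob$name[(cuts[k] + 1):cuts[k + 1]])
  lens <- vapply(blocks, length, integer(1))
  list(n_shared = m, blocks = blocks, n_blocks = length(blocks),
       breakpoints = length(blocks) - 1L, longest_block = max(lens),
       collinear_fraction = sum(lens[lens >= 2]) / m)
}
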