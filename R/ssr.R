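# Perfect microsatellite (SSR) mining with MISA-style thresholds, genomic
# context classification, motif presence/absence matrices and hierarchical
# clustering of species by shared motifs.

#' Default SSR copy-number thresholds
#'
#' Minimum copy numbers by repeat-unit length: 10 for mononucleotides, 6 for
#' dinucleotides, 5 for tri- and tetranucleotides, 3 for penta- through
#' decanucleotides.
#'
#' @return named integer vector over unit lengths 1..10
#' @export
ssr_thresholds <- function() {
  setNames(c(10L, 6L, 5L, 5L, 3L, 3L, 3L, 3L, 3L, 3L), as.character(1:10))
}

#' Lexicographically minimal rotation of a repeat motif
#'
#' Strands are not collapsed: A and T homopolymers stay distinct.
#'
#' @param motif repeat unit string
#' @return canonical rotation
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    if (u <= 1) return(m)
    rot <- vapply(seq_len(u), function(k)
      paste0(substr(m, k, u), substr(m, 1, k - 1)), "")
    min(rot)
  }, "", USE.NAMES = FALSE)
}

#' Find perfect SSRs in a sequence
#'
#' Reports all maximal perfect tandem repeats whose copy number meets the
#' threshold for their unit length.  Runs are reported once, at their
#' primitive unit and leftmost phase, with complete copies only; only
#' interruption-free (perfect) repeats are considered, and motifs containing
#' ambiguous bases are excluded.
#'
#' @param sequence nucleotide string
#' @param thresholds named vector of minimum copies per unit length
#'   (default [ssr_thresholds()])
#' @param species_id identifier stored with each locus
#' @return data frame: species_id, motif, canonical_motif, unit_len, copies,
#'   start, end (0-based half-open)
#' @export
find_ssrs <- function(sequence, thresholds = ssr_thresholds(),
                      species_id = NA_character_) {
  sequence <- toupper(sequence)
  max_u <- max(as.integer(names(thresholds)))
  mins <- rep(.Machine$integer.max, max_u)
  mins[as.integer(names(thresholds))] <- as.integer(thresholds)
  hits <- ssr_scan_cpp(sequence, mins)
  out <- data.frame(species_id = rep(species_id, nrow(hits)),
                    motif = hits$motif,
                    canonical_motif = canonical_motif(hits$motif),
                    unit_len = hits$unit_len, copies = hits$copies,
                    start = hits$start0,
                    end = hits$start0 + hits$unit_len * hits$copies,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

#' Classify the genomic context of SSR loci
#'
#' Labels each locus by the annotation containing its start position:
#' `CDS` if the start lies in an exon of a CDS feature, `intron` if in an
#' intron of any feature, otherwise `IGS` (intergenic spacer).  When features
#' overlap the priority is CDS > intron > IGS.
#'
#' @param loci data frame from [find_ssrs()] (uses the `start` column)
#' @param record the annotated [plastome_record()]
#' @return `loci` with a `context` column added
#' @export
classify_context <- function(loci, record) {
  n <- nchar(record$sequence)
  if (nrow(loci) > 0 && (any(loci$start < 0) || any(loci$start >= n)))
    stop("locus outside genome bounds")
  in_any <- function(pos, ivs) {
    if (nrow(ivs) == 0) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(ivs)))
      out <- out | (pos >= ivs[i, 1] & pos < ivs[i, 2])
    out
  }
  exon_cds <- do.call(rbind, lapply(record$genes, function(g)
    if (g$feature_class == "CDS") g$exons else NULL))
  introns <- do.call(rbind, lapply(record$genes, gene_introns))
  if (is.null(exon_cds)) exon_cds <- matrix(integer(0), ncol = 2)
  if (is.null(introns)) introns <- matrix(integer(0), ncol = 2)
  ctx <- rep("IGS", nrow(loci))
  ctx[in_any(loci$start, introns)] <- "intron"
  ctx[in_any(loci$start, exon_cds)] <- "CDS"
  loci$context <- ctx
  loci
}

#' Species x motif presence/absence matrix
#'
#' @param all_loci data frame of loci for two or more species (needs columns
#'   `species_id` and `canonical_motif`)
#' @return binary matrix, species in row-name order, motifs in lexicographic
#'   column order, with attribute `conserved` naming motifs present in at
#'   least 90% of species
#' @export
motif_presence_matrix <- function(all_loci) {
  sp <- sort(unique(all_loci$species_id))
  if (length(sp) < 2) stop("need at least 2 species")
  motifs <- sort(unique(all_loci$canonical_motif))
  m <- matrix(0L, length(sp), length(motifs), dimnames = list(sp, motifs))
  idx <- cbind(match(all_loci$species_id, sp),
               match(all_loci$canonical_motif, motifs))
  m[unique(idx)] <- 1L
  attr(m, "conserved") <- motifs[colMeans(m) >= 0.9]
  m
}

#' Cluster species by SSR motif presence/absence
#'
#' Agglomerative clustering with Jaccard distance and average linkage
#' (UPGMA); species-name order breaks ties deterministically.  Species with
#' identical profiles merge at height 0.
#'
#' @param m binary matrix from [motif_presence_matrix()]
#' @return list with `tree` (an `ape::phylo` dendrogram) and `newick` string
#' @export
cluster_species <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 1) stop("need >= 2 species and >= 1 motif")
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- vegan::vegdist(m, method = "jaccard", binary = TRUE)
  d[!is.finite(d)] <- 0                      # identical all-zero profiles
  hc <- hclust(d, method = "average")
  tree <- ape::as.phylo(hc)
  list(tree = tree, newick = ape::write.tree(tree))
}
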