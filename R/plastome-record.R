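# Core containers for one annotated plastome.  Coordinates are 0-based
# half-open throughout the package; GenBank I/O converts to and from the
# 1-based inclusive convention at the file boundary.

#' Construct a gene annotation
#'
#' @param name gene name (non-empty)
#' @param feature_class one of `"CDS"`, `"tRNA"`, `"rRNA"`
#' @param strand `"+"` or `"-"`
#' @param exons two-column matrix (start, end), 0-based half-open, in genomic
#'   coordinate order; introns are the gaps between consecutive exons
#' @return an object of class `gene_annotation`
#' @export
gene_annotation <- function(name, feature_class, strand, exons) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene name must be a non-empty string")
  feature_class <- match.arg(feature_class, c("CDS", "tRNA", "rRNA"))
  strand <- match.arg(strand, c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2] <= exons[, 1]))
    stop("exon intervals must be non-empty half-open [start, end)")
  if (nrow(exons) > 1) {
    o <- order(exons[, 1])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1, 1] < exons[-nrow(exons), 2]))
      stop("exons overlap in gene ", name)
  }
  structure(list(name = name, feature_class = feature_class,
                 strand = strand, exons = exons),
            class = "gene_annotation")
}

# intron intervals derived from the exon structure
gene_introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2) return(matrix(integer(0), ncol = 2))
  cbind(start = ex[-nrow(ex), 2], end = ex[-1, 1])
}

#' Construct a plastome record
#'
#' @param species_id species identifier
#' @param sequence circular nucleotide string over A,C,G,T,N (uppercased)
#' @param genes list of [gene_annotation()] objects
#' @param boundaries optional [region_boundaries()] object
#' @return an object of class `plastome_record`
#' @export
plastome_record <- function(species_id, sequence, genes = list(), boundaries = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence)) stop("sequence alphabet must be A,C,G,T,N")
  n <- nchar(sequence)
  for (g in genes) {
    if (any(g$exons < 0) || any(g$exons > n))
      stop("annotation of ", g$name, " outside [0, ", n, ")")
  }
  structure(list(species_id = species_id, sequence = sequence,
                 genes = genes, boundaries = boundaries),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat("<plastome_record> ", x$species_id, ": ", nchar(x$sequence), " bp, ",
      length(x$genes), " features",
      if (!is.null(x$boundaries)) " (quadripartite)" else "", "\n", sep = "")
  invisible(x)
}

#' Construct quadripartite region boundaries
#'
#' Intervals are 0-based half-open on the circle oriented LSC, IRb, SSC, IRa.
#'
#' @param lsc,irb,ssc,ira length-2 integer vectors (start, end); an interval
#'   with end <= start wraps past the origin
#' @return an object of class `region_boundaries`
#' @export
region_boundaries <- function(lsc, irb, ssc, ira) {
  structure(list(lsc = as.integer(lsc), irb = as.integer(irb),
                 ssc = as.integer(ssc), ira = as.integer(ira)),
            class = "region_boundaries")
}

# interval length on a circle of size n (end <= start wraps)
interval_len <- function(iv, n) {
  (iv[2] - iv[1]) %% n
}

#' Region lengths implied by a set of boundaries
#' @param b a [region_boundaries()] object
#' @param n genome length in bp
#' @return named vector (lsc, irb, ssc, ira)
#' @export
region_lengths <- function(b, n) {
  vapply(b[c("lsc", "irb", "ssc", "ira")], interval_len, numeric(1), n = n)
}

# substring on the circle, 0-based half-open with wrap
circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  start <- start %% n; end <- end %% n
  if (end > start) substr(seq, start + 1, end)
  else paste0(substr(seq, start + 1, n), substr(seq, 1, end))
}
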