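# Concatenated alignments, Jukes-Cantor distances, Saitou-Nei neighbor
# joining and per-genus branch-rate summaries.  Trees are ape "phylo"
# objects and serialize to Newick through ape.

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in lexicographic gene order; species missing a
#' gene are padded with gaps.  A column-occupancy filter optionally removes
#' sparse columns.
#'
#' @param per_gene named list: gene -> named character vector of equal-length
#'   aligned sequences (names = species)
#' @param min_occupancy drop columns with less than this fraction of
#'   non-gap characters (default 0.5); set to 0 to keep everything
#' @return list with `alignment` (named character vector per species),
#'   `partitions` (data frame gene/start/end, 1-based, pre-filter) and
#'   `kept_columns`
#' @export
concat_alignment <- function(per_gene, min_occupancy = 0.5) {
  if (length(per_gene) == 0) stop("empty alignment set")
  genes <- sort(names(per_gene))
  species <- sort(unique(unlist(lapply(per_gene, names))))
  widths <- vapply(genes, function(g) {
    w <- unique(nchar(per_gene[[g]]))
    if (length(w) != 1) stop("unequal row lengths in gene ", g)
    w
  }, numeric(1))
  ends <- cumsum(widths)
  starts <- c(1, head(ends, -1) + 1)
  rows <- vapply(species, function(sp) {
    paste(vapply(genes, function(g) {
      s <- per_gene[[g]]
      if (sp %in% names(s)) s[[sp]] else strrep("-", widths[[g]])
    }, ""), collapse = "")
  }, "")
  m <- do.call(rbind, strsplit(rows, ""))
  occ <- colMeans(m != "-")
  keep <- occ >= min_occupancy
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(rows) <- species
  list(alignment = rows,
       partitions = data.frame(gene = genes, start = starts, end = ends,
                               stringsAsFactors = FALSE),
       kept_columns = which(keep))
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise deletion of gap/ambiguous columns; the p-distance is corrected
#' as d = -(3/4) log(1 - 4p/3).  Pairs with p >= 3/4 or no shared ungapped
#' columns are flagged (NA).
#'
#' @param alignment named character vector of equal-length sequences
#' @return list of class `distance_matrix`: `taxa`, `d` (symmetric matrix,
#'   zero diagonal, NA = flagged)
#' @export
jc_distance <- function(alignment) {
  taxa <- names(alignment)
  if (length(taxa) < 2) stop("need at least 2 taxa")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  good <- m %in% c("A", "C", "G", "T")
  dim(good) <- dim(m)
  k <- length(taxa)
  d <- matrix(0, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      use <- good[i, ] & good[j, ]
      n <- sum(use)
      if (n == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
      p <- sum(m[i, use] != m[j, use]) / n
      d[i, j] <- d[j, i] <-
        if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
    }
  }
  structure(list(taxa = taxa, d = d), class = "distance_matrix")
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classic NJ with deterministic tie-breaking (the lowest-index pair in the
#' current matrix is merged on ties).  Negative branch lengths are clamped to
#' zero and the clamped deficit recorded in the `clamped` attribute.
#'
#' @param dm a `distance_matrix` (or plain symmetric matrix with dimnames)
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  taxa <- rownames(d)
  k <- nrow(d)
  if (k < 3) stop("need at least 3 taxa")
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
    stop("non-finite distances for pairs: ",
         paste(apply(bad, 1, function(ij)
           paste(taxa[ij[1]], taxa[ij[2]], sep = "-")), collapse = ", "))
  }
  n_tip <- k
  # node bookkeeping for the ape edge matrix
  labels <- taxa
  node_ids <- seq_len(n_tip)
  next_node <- 2L * n_tip - 2L            # internal ids count down from root
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  clamped <- 0
  active <- d
  ids <- node_ids
  while (nrow(active) > 2) {
    r <- nrow(active)
    rs <- rowSums(active)
    q <- (r - 2) * active - outer(rs, rs, "+")
    diag(q) <- Inf
    # lowest-index pair on ties: column-major which.min is deterministic,
    # but prefer (i, j) with smallest i then j in the upper triangle
    q[lower.tri(q)] <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- 0.5 * active[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- active[i, j] - li
    if (li < 0) { clamped <- clamped - li; li <- 0 }
    if (lj < 0) { clamped <- clamped - lj; lj <- 0 }
    new_id <- next_node; next_node <- next_node - 1L
    edges <- rbind(edges, c(new_id, ids[i]), c(new_id, ids[j]))
    lens <- c(lens, li, lj)
    nd <- 0.5 * (active[i, -c(i, j)] + active[j, -c(i, j)] - active[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    active2 <- active[keep, keep, drop = FALSE]
    active2 <- rbind(cbind(active2, nd), c(nd, 0))
    ids <- c(ids[keep], new_id)
    active <- active2
  }
  # two nodes remain; the last-created internal node (ids[2]) absorbs the
  # final edge, giving the usual unrooted NJ topology
  edges <- rbind(edges, c(ids[2], ids[1]))
  lens <- c(lens, active[1, 2])
  n_internal <- max(edges) - n_tip
  tr <- list(edge = edges, edge.length = lens, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  tr <- renumber_phylo(tr, n_tip)
  attr(tr, "clamped") <- clamped
  ape::reorder.phylo(tr, "cladewise")
}

# renumber internal nodes so ape conventions hold (root = n_tip + 1)
renumber_phylo <- function(tr, n_tip) {
  internal <- sort(unique(tr$edge[tr$edge > n_tip]))
  # root = node that never appears as a child
  children <- tr$edge[, 2]
  root <- setdiff(internal, children)
  ord <- c(root, setdiff(internal, root))
  map <- integer(max(internal))
  map[ord] <- n_tip + seq_along(ord)
  tr$edge[tr$edge > n_tip] <- map[tr$edge[tr$edge > n_tip]]
  tr
}

#' Per-genus terminal branch-length summary
#'
#' @param tree an `ape::phylo` tree with branch lengths
#' @param genus_map named character vector: species (tip label) -> genus
#' @return data frame: genus, n_tips, mean and SD of terminal branch lengths
#'   (SD is NA for singleton genera)
#' @export
branch_rate_summary <- function(tree, genus_map) {
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(genus_map))
  if (length(unmapped) > 0)
    stop("unmapped leaves: ", paste(unmapped, collapse = ", "))
  tip_edge <- match(seq_along(tips), tree$edge[, 2])
  term_len <- tree$edge.length[tip_edge]
  genus <- genus_map[tips]
  agg <- split(term_len, genus)
  out <- data.frame(genus = names(agg),
                    n_tips = vapply(agg, length, integer(1)),
                    mean_branch = vapply(agg, mean, numeric(1)),
                    sd_branch = vapply(agg, function(x)
                      if (length(x) > 1) sd(x) else NA_real_, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$genus), , drop = FALSE]
}
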