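# Classical correspondence analysis of a nonnegative genes x codons table
# (by default per-gene RSCU rows), with inertia accounting.

#' Correspondence analysis of a nonnegative table
#'
#' Classical CA: the table is scaled to proportions P, standardized residuals
#' S = Dr^(-1/2) (P - r c') Dc^(-1/2) are formed from the row and column
#' masses, and the SVD of S yields principal coordinates (mass-scaled
#' singular vectors times singular values).  Total inertia is the sum of
#' squared singular values and equals the chi-square statistic of the table
#' divided by its grand total.  Axes are sign-fixed so that the
#' largest-magnitude column loading on each axis is positive; all-zero rows
#' and columns are pruned (and recorded) before analysis.
#'
#' @param x nonnegative matrix (rows = genes, columns = codons); NA entries
#'   are treated as zero (unobserved families completed with zeros)
#' @param n_axes number of axes to retain (default all)
#' @return list of class `coa_result` with `row_coords`, `col_coords`,
#'   `singular_values`, `total_inertia`, `axis_pct`, `pruned_rows`,
#'   `pruned_cols`
#' @export
coa <- function(x, n_axes = NULL) {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  if (any(x < 0)) stop("table must be nonnegative")
  pr <- rowSums(x) == 0
  pc <- colSums(x) == 0
  pruned_rows <- rownames(x)[pr]; pruned_cols <- colnames(x)[pc]
  x <- x[!pr, !pc, drop = FALSE]
  if (nrow(x) == 0 || ncol(x) == 0) stop("table empty after pruning")
  N <- sum(x)
  P <- x / N
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r), nrow = length(r)) %*% (P - r %o% cc) %*%
    diag(1 / sqrt(cc), nrow = length(cc))
  sv <- svd(S)
  k_max <- min(nrow(x), ncol(x)) - 1
  tol <- max(dim(x)) * max(sv$d, 0) * .Machine$double.eps * 100
  keep <- which(sv$d > max(tol, 1e-12))
  keep <- keep[keep <= max(k_max, 0)]
  d <- sv$d[keep]
  total_inertia <- sum(sv$d[seq_len(max(k_max, 0))]^2)
  if (length(keep) == 0) {
    return(structure(list(
      row_coords = matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL)),
      col_coords = matrix(0, ncol(x), 0, dimnames = list(colnames(x), NULL)),
      singular_values = numeric(0), total_inertia = 0,
      axis_pct = numeric(0), pruned_rows = pruned_rows,
      pruned_cols = pruned_cols), class = "coa_result"))
  }
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude column loading positive per axis
  for (a in seq_along(keep)) {
    j <- which.max(abs(V[, a]))
    if (V[j, a] < 0) { V[, a] <- -V[, a]; U[, a] <- -U[, a] }
  }
  row_coords <- sweep(U, 1, sqrt(r), "/") %*% diag(d, length(d))
  col_coords <- sweep(V, 1, sqrt(cc), "/") %*% diag(d, length(d))
  ax <- paste0("Axis", seq_along(d))
  dimnames(row_coords) <- list(rownames(x), ax)
  dimnames(col_coords) <- list(colnames(x), ax)
  if (!is.null(n_axes)) {
    n_axes <- min(n_axes, length(d))
    row_coords <- row_coords[, seq_len(n_axes), drop = FALSE]
    col_coords <- col_coords[, seq_len(n_axes), drop = FALSE]
  }
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 singular_values = d, total_inertia = total_inertia,
                 axis_pct = 100 * d^2 / total_inertia,
                 pruned_rows = pruned_rows, pruned_cols = pruned_cols),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  cat("<coa_result> ", nrow(x$row_coords), " rows x ", nrow(x$col_coords),
      " cols; total inertia ", signif(x$total_inertia, 5), "\n", sep = "")
  if (length(x$axis_pct) > 0)
    cat("  axes: ", paste(sprintf("%.2f%%", x$axis_pct[seq_len(min(4, length(x$axis_pct)))]),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-gene RSCU matrix for correspondence analysis
#'
#' @param genes list of [gene_sequence()]
#' @param counts use raw codon counts instead of RSCU values
#' @return numeric matrix, genes x 59 informative codons (NA-free; codons of
#'   unobserved families set to 0)
#' @export
rscu_matrix <- function(genes, counts = FALSE) {
  info <- informative_codons()
  rows <- vapply(genes, function(g) {
    cc <- codon_counts(g)$counts
    if (counts) as.numeric(cc[info]) else {
      v <- rscu(cc)
      v[is.na(v)] <- 0
      as.numeric(v)
    }
  }, numeric(length(info)))
  m <- t(rows)
  dimnames(m) <- list(vapply(genes, `[[`, "", "gene_name"), info)
  m
}
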