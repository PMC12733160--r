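# Codon-usage-bias battery: codon counts, RSCU, Wright's effective number of
# codons with its expected GC3s curve, positional GC content, parity-rule-2
# indices and the GC12 ~ GC3 neutrality regression.

#' Codon counts for one coding sequence
#'
#' Stop codons are tallied separately and excluded from all bias statistics;
#' codons containing an ambiguous base are skipped and counted in `skipped`.
#'
#' @param x a [gene_sequence()] or an in-frame nucleotide string
#' @return list with `counts` (named integer vector over the 64 codons,
#'   stop entries always 0), `stops`, `skipped`
#' @export
codon_counts <- function(x) {
  cds <- if (inherits(x, "gene_sequence")) x$cds else toupper(x)
  stopifnot(nchar(cds) %% 3 == 0)
  cod <- codon_vector(cds)
  ok <- !grepl("[^ACGT]", cod)
  skipped <- sum(!ok)
  cod <- cod[ok]
  code <- genetic_code_11()
  is_stop <- code[cod] == "*"
  counts <- table(factor(cod[!is_stop], levels = all_codons()))
  list(counts = setNames(as.integer(counts), all_codons()),
       stops = sum(is_stop), skipped = skipped)
}

#' Relative synonymous codon usage
#'
#' For codon j in a family of n_i synonymous codons with family total X_i,
#' RSCU = x_j * n_i / X_i.  Met, Trp and stop codons are excluded (59-codon
#' convention); families with no observations are returned as NA.
#'
#' @param counts named codon count vector (as from [codon_counts()]`$counts`)
#' @return named numeric vector over the 59 informative codons
#' @export
rscu <- function(counts) {
  fam <- codon_families()
  out <- setNames(rep(NA_real_, length(informative_codons())),
                  informative_codons())
  for (aa in names(fam)) {
    cods <- fam[[aa]]
    if (length(cods) < 2) next                    # Met, Trp
    tot <- sum(counts[cods])
    if (tot == 0) next
    out[cods] <- counts[cods] * length(cods) / tot
  }
  out
}

# family sizes of the 18 synonymously variable amino acids
family_sizes <- function() {
  fam <- codon_families()
  sz <- vapply(fam, length, integer(1))
  sz[sz >= 2]
}

#' Wright's effective number of codons (ENC)
#'
#' Per observed family, the codon homozygosity is estimated as
#' F = (n * sum(p^2) - 1) / (n - 1) (the unbiased form; `unbiased = FALSE`
#' uses raw sum(p^2)), families with n < 2 or F <= 0 are omitted, and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 over the family-size class averages.
#' A missing threefold class is imputed as (F2 + F4)/2; any other missing
#' class leaves ENC undefined (NA).  The estimate is capped at 61.
#'
#' @param counts named codon count vector
#' @param unbiased use the unbiased homozygosity estimator (default)
#' @return ENC in `[20, 61]`, or NA when undefined
#' @export
enc <- function(counts, unbiased = TRUE) {
  fam <- codon_families()
  sz <- family_sizes()
  fhat <- lapply(names(sz), function(aa) {
    n <- sum(counts[fam[[aa]]])
    if (n < 2) return(NULL)
    p <- counts[fam[[aa]]] / n
    f <- if (unbiased) (n * sum(p^2) - 1) / (n - 1) else sum(p^2)
    if (f <= 0) return(NULL)
    c(k = sz[[aa]], f = f)
  })
  fhat <- do.call(rbind, fhat)
  if (is.null(fhat)) return(NA_real_)
  fbar <- tapply(fhat[, "f"], fhat[, "k"], mean)
  need <- c("2", "3", "4", "6")
  if (!("3" %in% names(fbar)) && all(c("2", "4") %in% names(fbar)))
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  if (!all(need %in% names(fbar))) return(NA_real_)
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
  min(val, 61)
}

#' Expected ENC under a purely GC3s-driven mutation model
#'
#' ENC* = 2 + s + 29 / (s^2 + (1 - s)^2) with s the GC content at
#' synonymous third positions.
#'
#' @param gc3s fraction in `[0, 1]` (vectorized)
#' @return expected effective number of codons
#' @export
expected_enc <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1)) stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

# positional GC on a raw in-frame string (shared with region_stats)
positional_gc_string <- function(cds) {
  cod <- codon_vector(toupper(cds))
  cod <- cod[!grepl("[^ACGT]", cod)]
  code <- genetic_code_11()
  cod <- cod[code[cod] != "*"]                   # non-stop codons
  if (length(cod) == 0)
    return(list(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
                gc3s = NA_real_, gc12 = NA_real_, flag = "no informative codons"))
  gcfrac <- function(ch) mean(ch %in% c("G", "C"))
  gc1 <- gcfrac(substr(cod, 1, 1))
  gc2 <- gcfrac(substr(cod, 2, 2))
  gc3 <- gcfrac(substr(cod, 3, 3))
  syn <- cod[cod %in% informative_codons()]
  gc3s <- if (length(syn) > 0) gcfrac(substr(syn, 3, 3)) else NA_real_
  list(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc3s = gc3s, gc12 = (gc1 + gc2) / 2,
       flag = if (length(syn) == 0) "no synonymously variable codons" else NA_character_)
}

#' Positional GC content of a coding sequence
#'
#' Fractions are computed over non-stop codons; `gc3s` additionally excludes
#' Met and Trp codons (synonymous third positions only) and `gc12` is the
#' mean of `gc1` and `gc2`.
#'
#' @param x a [gene_sequence()] or in-frame nucleotide string
#' @return list with `gc1`, `gc2`, `gc3`, `gc3s`, `gc12` and a `flag`
#' @export
positional_gc <- function(x) {
  cds <- if (inherits(x, "gene_sequence")) x$cds else x
  positional_gc_string(cds)
}

#' Parity-rule-2 indices
#'
#' Third-position base counts over the informative codons (non-stop,
#' excluding Met and Trp), returned as A3/(A3+T3) and G3/(G3+C3).  Under
#' strand-compositional equilibrium both coordinates equal 0.5.
#'
#' @param x a [gene_sequence()], in-frame nucleotide string, or a named
#'   codon count vector
#' @param fourfold_only restrict to fourfold-degenerate families
#' @return list with `a3_ratio`, `g3_ratio` and the raw `a3`,`t3`,`g3`,`c3`
#' @export
pr2_indices <- function(x, fourfold_only = FALSE) {
  counts <- if (is.numeric(x)) x else codon_counts(x)$counts
  info <- informative_codons()
  if (fourfold_only) {
    fam <- codon_families()
    info <- unlist(fam[vapply(fam, length, integer(1)) == 4], use.names = FALSE)
  }
  third <- substr(info, 3, 3)
  tot <- function(b) sum(counts[info[third == b]])
  a3 <- tot("A"); t3 <- tot("T"); g3 <- tot("G"); c3 <- tot("C")
  list(a3_ratio = if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_,
       g3_ratio = if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_,
       a3 = a3, t3 = t3, g3 = g3, c3 = c3)
}

#' Full codon-usage profile of one gene
#'
#' @param gene a [gene_sequence()]
#' @return list combining counts, RSCU, ENC, positional GC and PR2 fields
#' @export
codon_profile <- function(gene) {
  cc <- codon_counts(gene)
  pg <- positional_gc(gene)
  pr <- pr2_indices(cc$counts)
  list(species_id = gene$species_id, gene_name = gene$gene_name,
       category = gene$category, counts = cc$counts, stops = cc$stops,
       rscu = rscu(cc$counts), enc = enc(cc$counts),
       gc1 = pg$gc1, gc2 = pg$gc2, gc3 = pg$gc3, gc3s = pg$gc3s,
       gc12 = pg$gc12, a3_ratio = pr$a3_ratio, g3_ratio = pr$g3_ratio,
       a3 = pr$a3, t3 = pr$t3, g3 = pr$g3, c3 = pr$c3)
}

#' Per-gene codon-usage table for a set of genes
#'
#' @param genes list of [gene_sequence()]
#' @return data frame, one row per gene, with ENC, positional GC, PR2
#'   coordinates and the 59 RSCU columns
#' @export
codon_profile_table <- function(genes) {
  rows <- lapply(genes, function(g) {
    p <- codon_profile(g)
    base <- data.frame(species_id = p$species_id, gene_name = p$gene_name,
                       category = p$category, enc = p$enc, gc1 = p$gc1,
                       gc2 = p$gc2, gc3 = p$gc3, gc3s = p$gc3s, gc12 = p$gc12,
                       a3_ratio = p$a3_ratio, g3_ratio = p$g3_ratio,
                       stringsAsFactors = FALSE)
    cbind(base, as.data.frame(as.list(p$rscu), optional = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 on GC3.  A slope near 1 indicates
#' mutation-dominated codon usage; a slope near 0 indicates selection.
#'
#' @param gc12,gc3 numeric vectors per gene (NA pairs dropped)
#' @return list with `slope`, `intercept`, `r_squared`, `n_genes`,
#'   `mean_gc12`, `sd_gc12`, `mean_gc3`, `sd_gc3` and a `flag`
#' @export
neutrality_fit <- function(gc12, gc3) {
  ok <- is.finite(gc12) & is.finite(gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  n <- length(gc12)
  if (n < 2) stop("neutrality regression needs at least 2 genes")
  vx <- var(gc3)
  flag <- NA_character_
  if (vx == 0) {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
    flag <- "zero variance in GC3"
  } else {
    slope <- cov(gc12, gc3) / vx
    intercept <- mean(gc12) - slope * mean(gc3)
    vy <- var(gc12)
    r2 <- if (vy == 0) 0 else cov(gc12, gc3)^2 / (vx * vy)
  }
  list(slope = slope, intercept = intercept, r_squared = r2, n_genes = n,
       mean_gc12 = mean(gc12), sd_gc12 = sd(gc12),
       mean_gc3 = mean(gc3), sd_gc3 = sd(gc3), flag = flag)
}

#' Per-species codon-usage summary
#'
#' Unweighted means over retained genes of ENC, GC3s, GC12 and the PR2
#' coordinates, plus the species-level neutrality fit.
#'
#' @param profile_table output of [codon_profile_table()]
#' @return data frame, one row per species
#' @export
species_codon_summary <- function(profile_table) {
  sp <- split(profile_table, profile_table$species_id)
  rows <- lapply(sp, function(d) {
    fit <- if (sum(is.finite(d$gc12) & is.finite(d$gc3)) >= 2)
      neutrality_fit(d$gc12, d$gc3) else NULL
    data.frame(species_id = d$species_id[1], n_genes = nrow(d),
               mean_enc = mean(d$enc, na.rm = TRUE),
               mean_gc3s = mean(d$gc3s, na.rm = TRUE),
               mean_gc12 = mean(d$gc12, na.rm = TRUE),
               mean_a3_ratio = mean(d$a3_ratio, na.rm = TRUE),
               mean_g3_ratio = mean(d$g3_ratio, na.rm = TRUE),
               neutrality_slope = if (is.null(fit)) NA_real_ else fit$slope,
               neutrality_r2 = if (is.null(fit)) NA_real_ else fit$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
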