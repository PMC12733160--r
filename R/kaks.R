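# Protein-guided pairwise codon alignment, Nei-Gojobori (NG86) Ka/Ks
# estimation with pathway averaging and Jukes-Cantor correction, and the
# selection-pressure category statistics.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V","*","X")

# strip a terminal stop codon, if present
strip_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3) {
    last <- substr(cds, n - 2, n)
    code <- genetic_code_11()
    if (!is.na(code[last]) && code[[last]] == "*") return(substr(cds, 1, n - 3))
  }
  cds
}

#' Protein-guided pairwise codon alignment
#'
#' Globally aligns the translations of two orthologous coding sequences
#' (match +1, mismatch -1, gap open -5, gap extend -1; deterministic
#' traceback preferring diagonal over up over left), back-translates the
#' alignment to codons, and removes every column containing a gap (complete
#' deletion).  Terminal stop codons are stripped before alignment.
#'
#' @param a,b [gene_sequence()] objects with the same `gene_name`
#' @return object of class `codon_alignment`: `gene_name`, `species_pair`,
#'   `codons_a`, `codons_b` (equal-length codon vectors, gap-free)
#' @export
codon_align <- function(a, b) {
  if (!identical(tolower(a$gene_name), tolower(b$gene_name)))
    stop("gene names differ: ", a$gene_name, " vs ", b$gene_name)
  ca <- codon_vector(strip_stop(a$cds))
  cb <- codon_vector(strip_stop(b$cds))
  pa <- genetic_code_11()[ca]; pb <- genetic_code_11()[cb]
  pa[is.na(pa)] <- "X"; pb[is.na(pb)] <- "X"
  ia <- match(pa, AA_ALPHABET); ib <- match(pb, AA_ALPHABET)
  aln <- nw_align_cpp(ia, ib, 1, -1, 5, 1)
  keep <- aln$a > 0 & aln$b > 0
  codons_a <- ca[aln$a[keep]]
  codons_b <- cb[aln$b[keep]]
  ok <- !grepl("[^ACGT]", codons_a) & !grepl("[^ACGT]", codons_b)
  codons_a <- codons_a[ok]; codons_b <- codons_b[ok]
  if (length(codons_a) == 0) stop("no alignable codons for ", a$gene_name)
  structure(list(gene_name = a$gene_name,
                 species_pair = c(a$species_id, b$species_id),
                 codons_a = codons_a, codons_b = codons_b,
                 score = aln$score),
            class = "codon_alignment")
}

#' NG86 Ka/Ks estimation on a codon alignment
#'
#' Synonymous site fractions per codon are the per-position fractions of
#' one-step changes that preserve the amino acid (changes to stop codons
#' count as nonsynonymous), averaged between the two sequences.  Observed
#' differences are averaged over all stop-free mutational pathways between
#' each codon pair; codon pairs with no stop-free pathway are skipped and
#' counted.  Proportions are corrected with Jukes-Cantor
#' d = -(3/4) log(1 - 4p/3); the ratio is undefined when Ks = 0 or a
#' proportion reaches 3/4.
#'
#' @param aln a codon alignment from [codon_align()]
#' @return object of class `kaks_pair`: `ka`, `ks`, `ratio`, `category`
#'   (strong purifying / relaxed purifying / positive / undefined), site and
#'   difference counts, `n_codons`, `n_skipped`
#' @export
ng86 <- function(aln) {
  tab <- ng86_tables()
  pair_idx <- cbind(aln$codons_a, aln$codons_b)
  sd_i <- tab$sd[pair_idx]; nd_i <- tab$nd[pair_idx]
  skip <- is.na(sd_i)
  n_skipped <- sum(skip)
  ca <- aln$codons_a[!skip]; cb <- aln$codons_b[!skip]
  L <- length(ca)
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- 3 * L - S
  Sd <- sum(sd_i[!skip]); Nd <- sum(nd_i[!skip])
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  ks <- jc(pS); ka <- jc(pN)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  category <- if (is.na(ratio)) "undefined"
  else if (ratio < 0.5) "strong purifying"
  else if (ratio <= 1) "relaxed purifying"
  else "positive"
  structure(list(gene_name = aln$gene_name, species_pair = aln$species_pair,
                 ka = ka, ks = ks, ratio = ratio, category = category,
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 n_codons = L, n_skipped = n_skipped),
            class = "kaks_pair")
}

#' All pairwise Ka/Ks comparisons over a gene set
#'
#' Orthologs are matched by gene name (case-insensitive); every unordered
#' species pair sharing a gene is aligned and scored.
#'
#' @param genes list of [gene_sequence()] across species
#' @return data frame: gene, species_a, species_b, functional category, ka,
#'   ks, ratio, selection class
#' @export
kaks_pairs <- function(genes) {
  by_gene <- split(genes, tolower(vapply(genes, `[[`, "", "gene_name")))
  rows <- list()
  for (gset in by_gene) {
    if (length(gset) < 2) next
    for (i in seq_len(length(gset) - 1)) {
      for (j in (i + 1):length(gset)) {
        kp <- tryCatch(ng86(codon_align(gset[[i]], gset[[j]])),
                       error = function(e) NULL)
        if (is.null(kp)) next
        rows[[length(rows) + 1]] <- data.frame(
          gene = kp$gene_name, species_a = kp$species_pair[1],
          species_b = kp$species_pair[2], category = gset[[i]]$category,
          ka = kp$ka, ks = kp$ks, ratio = kp$ratio, selection = kp$category,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0), species_a = character(0),
                                      species_b = character(0), category = character(0),
                                      ka = numeric(0), ks = numeric(0),
                                      ratio = numeric(0), selection = character(0))
  rownames(out) <- NULL
  out
}

# Cohen's d with pooled standard deviation, first minus second
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (!is.finite(sp) || sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Selection-pressure summary over Ka/Ks pairs
#'
#' Removes outlier pairs (ratio above `max_ratio`), tabulates
#' selection-class fractions, summarizes each functional category
#' (mean/median ratio, one-sample t-test against the neutral expectation 1
#' with Bonferroni correction over categories, Pearson r between Ka and Ks),
#' and runs all between-category Wilcoxon rank-sum tests with Bonferroni
#' correction and Cohen's d effect sizes.
#'
#' @param pairs data frame from [kaks_pairs()]
#' @param max_ratio outlier cap on the ratio (default 10)
#' @return list with `n_pairs_pre`, `n_pairs_defined`, `outliers_removed`,
#'   `class_fractions`, `category_stats`, `pairwise_tests`
#' @export
selection_summary <- function(pairs, max_ratio = 10) {
  n_pre <- nrow(pairs)
  def <- pairs[!is.na(pairs$ratio), , drop = FALSE]
  out_n <- sum(def$ratio > max_ratio)
  def <- def[def$ratio <= max_ratio, , drop = FALSE]
  if (nrow(def) == 0) stop("no defined Ka/Ks pairs")
  cls <- factor(def$selection,
                levels = c("strong purifying", "relaxed purifying", "positive"))
  class_fractions <- as.numeric(table(cls)) / nrow(def)
  names(class_fractions) <- levels(cls)

  cats <- split(def, def$category)
  cat_rows <- lapply(cats, function(d) {
    testable <- nrow(d) >= 2 && sd(d$ratio) > 0
    tt <- if (testable) t.test(d$ratio, mu = 1) else NULL
    r <- if (nrow(d) >= 3 && sd(d$ka) > 0 && sd(d$ks) > 0)
      cor(d$ka, d$ks, method = "pearson") else NA_real_
    data.frame(category = d$category[1], n = nrow(d),
               mean_ratio = mean(d$ratio), median_ratio = median(d$ratio),
               mean_ka = mean(d$ka), mean_ks = mean(d$ks),
               frac_positive = mean(d$selection == "positive"),
               t_stat = if (testable) unname(tt$statistic) else NA_real_,
               p_vs_neutral = if (testable) tt$p.value else NA_real_,
               pearson_r = r, tested = testable, stringsAsFactors = FALSE)
  })
  category_stats <- do.call(rbind, cat_rows)
  rownames(category_stats) <- NULL
  n_tested <- sum(category_stats$tested)
  category_stats$p_bonferroni <-
    pmin(category_stats$p_vs_neutral * n_tested, 1)

  cn <- category_stats$category
  pw <- list()
  if (length(cn) >= 2) {
    for (i in seq_len(length(cn) - 1)) {
      for (j in (i + 1):length(cn)) {
        x <- cats[[cn[i]]]$ratio; y <- cats[[cn[j]]]$ratio
        if (length(x) < 2 || length(y) < 2) next
        wt <- suppressWarnings(wilcox.test(x, y))
        pw[[length(pw) + 1]] <- data.frame(
          category_a = cn[i], category_b = cn[j],
          mean_diff = mean(x) - mean(y),
          w_stat = unname(wt$statistic), p = wt$p.value,
          cohens_d = cohens_d(x, y), stringsAsFactors = FALSE)
      }
    }
  }
  pairwise_tests <- if (length(pw) > 0) do.call(rbind, pw) else
    data.frame(category_a = character(0), category_b = character(0),
               mean_diff = numeric(0), w_stat = numeric(0), p = numeric(0),
               cohens_d = numeric(0))
  if (nrow(pairwise_tests) > 0)
    pairwise_tests$p_bonferroni <- pmin(pairwise_tests$p * nrow(pairwise_tests), 1)

  list(n_pairs_pre = n_pre, n_pairs_defined = nrow(def),
       outliers_removed = out_n, class_fractions = class_fractions,
       category_stats = category_stats, pairwise_tests = pairwise_tests)
}
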