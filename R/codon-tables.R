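# Genetic-code machinery shared by the codon-usage and Ka/Ks stages.
# Translation uses the bacterial/plant-plastid code (NCBI table 11), whose
# codon-to-amino-acid map over the 64 codons is identical to the standard
# code; the tables below are derived from Biostrings at load time.

.pe <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' All 64 codons in a fixed lexicographic order
#' @return character vector of 64 codons (A < C < G < T)
#' @export
all_codons <- function() {
  if (is.null(.pe$codons)) {
    g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES, stringsAsFactors = FALSE)
    .pe$codons <- sort(paste0(g$p1, g$p2, g$p3))
  }
  .pe$codons
}

#' Codon-to-amino-acid map under the plastid/bacterial code (table 11)
#' @return named character vector over the 64 codons; stops are `"*"`
#' @export
genetic_code_11 <- function() {
  if (is.null(.pe$code)) {
    gc <- Biostrings::getGeneticCode("11")
    .pe$code <- gc[all_codons()]
  }
  .pe$code
}

# sense codons with at least one synonymous alternative: all codons except
# stops, ATG (Met) and TGG (Trp) -- the 59-codon convention
informative_codons <- function() {
  code <- genetic_code_11()
  names(code)[code != "*" & !names(code) %in% c("ATG", "TGG")]
}

# list: amino acid -> codons, sense codons only
codon_families <- function() {
  if (is.null(.pe$fam)) {
    code <- genetic_code_11()
    sense <- code[code != "*"]
    .pe$fam <- split(names(sense), sense)
  }
  .pe$fam
}

# NG86 per-codon synonymous site fractions and pairwise difference tables.
# For a sense codon, each of the 9 one-step changes is synonymous iff the
# mutated codon is a sense codon for the same amino acid; changes to stop
# codons count as nonsynonymous so that S + N = 3 per codon exactly.
ng86_tables <- function() {
  if (!is.null(.pe$ng)) return(.pe$ng)
  code <- genetic_code_11()
  codons <- all_codons()
  nc <- length(codons)
  syn_sites <- setNames(numeric(nc), codons)
  for (cd in codons) {
    if (code[[cd]] == "*") { syn_sites[cd] <- NA_real_; next }
    s <- 0
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(BASES, sp[pos])) {
        alt <- sp; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (code[[alt]] != "*" && code[[alt]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[cd] <- s
  }
  # pathway-averaged synonymous/nonsynonymous differences between codon pairs
  sd_tab <- matrix(NA_real_, nc, nc, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  step_class <- function(from, to) {
    # classify one single-base step; NA if it passes through a stop
    if (code[[to]] == "*") return(NA_real_)
    if (code[[from]] == code[[to]]) 1 else 0       # 1 = synonymous
  }
  for (i in seq_len(nc)) {
    ci <- codons[i]
    if (code[[ci]] == "*") next
    si <- strsplit(ci, "")[[1]]
    for (j in seq_len(nc)) {
      cj <- codons[j]
      if (code[[cj]] == "*") next
      sj <- strsplit(cj, "")[[1]]
      diff_pos <- which(si != sj)
      nd <- length(diff_pos)
      if (nd == 0) { sd_tab[i, j] <- 0; nd_tab[i, j] <- 0; next }
      perms <- if (nd == 1) list(diff_pos) else
        if (nd == 2) list(diff_pos, rev(diff_pos)) else
          lapply(asplit(rbind(c(1,2,3),c(1,3,2),c(2,1,3),c(2,3,1),c(3,1,2),c(3,2,1)), 1),
                 function(o) diff_pos[o])
      tot_s <- 0; tot_n <- 0; n_legal <- 0
      for (ord in perms) {
        cur <- si; s_cnt <- 0; n_cnt <- 0; legal <- TRUE
        for (pos in ord) {
          nxt <- cur; nxt[pos] <- sj[pos]
          cls <- step_class(paste(cur, collapse = ""), paste(nxt, collapse = ""))
          if (is.na(cls)) { legal <- FALSE; break }
          if (cls == 1) s_cnt <- s_cnt + 1 else n_cnt <- n_cnt + 1
          cur <- nxt
        }
        if (legal) { tot_s <- tot_s + s_cnt; tot_n <- tot_n + n_cnt; n_legal <- n_legal + 1 }
      }
      if (n_legal > 0) {
        sd_tab[i, j] <- tot_s / n_legal
        nd_tab[i, j] <- tot_n / n_legal
      }                                   # else NA: no stop-free pathway
    }
  }
  .pe$ng <- list(syn_sites = syn_sites, sd = sd_tab, nd = nd_tab)
  .pe$ng
}

#' Translate an in-frame nucleotide sequence under the plastid code
#' @param cds nucleotide string, length divisible by 3
#' @return amino-acid string (stops as `"*"`)
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  if (nchar(cds) == 0) return("")
  cod <- codon_vector(cds)
  aa <- genetic_code_11()[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# split an in-frame sequence into its codons
codon_vector <- function(cds) {
  n <- nchar(cds)
  if (n == 0) return(character(0))
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Reverse complement of a nucleotide string
#' @param x nucleotide string over A,C,G,T,N
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
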