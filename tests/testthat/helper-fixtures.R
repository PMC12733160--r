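# Shared fixtures and independent oracles used across the suite.

random_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# small simulated plastome used by several files (desk-scale lengths)
small_sim_config <- function(seed = 1) {
  simulation_config(seed = seed, lsc_len = 9000, ssc_len = 700, ir_len = 2500,
                    n_genes_lsc = 8, n_genes_ssc = 0, n_genes_ir = 2)
}

# --- SSR oracle -------------------------------------------------------------
# Independent run-length-based enumerator of maximal perfect tandem repeats:
# complete copies only, primitive motifs, leftmost phase, per-unit thresholds.
ssr_oracle <- function(seq, thresholds = ssr_thresholds()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  out <- list()
  is_primitive <- function(m) {
    u <- nchar(m)
    for (d in seq_len(u - 1)) {
      if (u %% d != 0) next
      if (identical(strrep(substr(m, 1, d), u / d), m)) return(FALSE)
    }
    TRUE
  }
  for (u in as.integer(names(thresholds))) {
    if (n <= u) next
    eq <- ch[seq_len(n - u)] == ch[(u + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      ext <- r$lengths[k] + u
      cp <- ext %/% u
      if (cp < thresholds[[as.character(u)]]) next
      s <- starts[k]
      motif <- paste(ch[s:(s + u - 1)], collapse = "")
      if (!is_primitive(motif) || grepl("N", motif)) next
      out[[length(out) + 1]] <- data.frame(
        motif = motif, unit_len = u, copies = cp, start = s - 1L,
        end = s - 1L + cp * u, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(motif = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0), end = integer(0)))
  d <- do.call(rbind, out)
  d[order(d$start, d$unit_len), , drop = FALSE]
}

# slowest possible per-start enumerator, for short sequences only
ssr_oracle_naive <- function(seq, thresholds = ssr_thresholds()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  rows <- list()
  for (u in as.integer(names(thresholds))) {
    for (s in seq_len(max(n - 2 * u + 1, 0))) {
      # leftmost phase: position s-1 must break the period
      if (s > 1 && ch[s - 1] == ch[s - 1 + u]) next
      cp <- 1
      while (s + (cp + 1) * u - 1 <= n &&
             all(ch[s:(s + u - 1)] == ch[(s + cp * u):(s + (cp + 1) * u - 1)]))
        cp <- cp + 1
      if (cp < thresholds[[as.character(u)]]) next
      motif <- paste(ch[s:(s + u - 1)], collapse = "")
      prim <- TRUE
      for (d in seq_len(u - 1))
        if (u %% d == 0 && identical(strrep(substr(motif, 1, d), u / d), motif))
          prim <- FALSE
      if (!prim || grepl("N", motif)) next
      rows[[length(rows) + 1]] <- data.frame(
        motif = motif, unit_len = u, copies = cp, start = s - 1L,
        end = s - 1L + cp * u, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(motif = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0), end = integer(0)))
  d <- do.call(rbind, rows)
  d[order(d$start, d$unit_len), , drop = FALSE]
}

ssr_key <- function(d) {
  d <- d[order(d$start, d$unit_len), , drop = FALSE]
  paste(d$motif, d$unit_len, d$copies, d$start, d$end, sep = ":")
}

# --- alignment oracle -------------------------------------------------------
# Exhaustive enumeration of all global alignments of two short protein
# strings; gap of length L costs open + L*ext.
align_oracle_score <- function(a, b, match = 1, mismatch = -1,
                               open = 5, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, score + if (av[i] == bv[j]) match else mismatch, "D")
    if (i <= length(av))
      rec(i + 1, j, score - ext - if (prev == "U") 0 else open, "U")
    if (j <= length(bv))
      rec(i, j + 1, score - ext - if (prev == "L") 0 else open, "L")
  }
  rec(1, 1, 0, "D")
  best
}

# random in-frame stop-free CDS built from sense codons
random_sense_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- plastevo:::genetic_code_11()
  sense <- names(code)[code != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}
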