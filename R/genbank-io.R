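# GenBank flat-file and FASTA/TSV I/O for annotated plastomes.  The GenBank
# reader is deliberately minimal: it captures the LOCUS length, CDS/tRNA/rRNA
# features with join()/complement() locations and /gene qualifiers, and the
# ORIGIN sequence.  File coordinates are 1-based inclusive; internal
# coordinates are 0-based half-open.

#' Read a plastome from a file
#'
#' Dispatches on extension: `.gb`/`.gbk`/`.genbank` are parsed as GenBank
#' flat files; `.fa`/`.fasta`/`.fna` as FASTA, optionally with a sibling
#' annotation table (`<stem>.ann.tsv`, see [read_annotation_tsv()]) or one
#' passed explicitly.
#'
#' @param path input file
#' @param annotation optional annotation TSV path for FASTA input
#' @param species_id species identifier; defaults to the file stem / LOCUS name
#' @return a [plastome_record()]
#' @export
parse_plastome <- function(path, annotation = NULL, species_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gb", "gbk", "genbank")) {
    read_genbank(path, species_id = species_id)
  } else if (ext %in% c("fa", "fasta", "fna")) {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1) stop("expected a single FASTA record in ", path)
    if (is.null(species_id))
      species_id <- sub("\\s.*$", "", names(ss)[1])
    if (is.null(annotation)) {
      cand <- paste0(tools::file_path_sans_ext(path), ".ann.tsv")
      if (file.exists(cand)) annotation <- cand
    }
    genes <- if (!is.null(annotation)) read_annotation_tsv(annotation) else list()
    plastome_record(species_id, as.character(ss[[1]]), genes)
  } else {
    stop("unrecognized plastome file extension: ", ext)
  }
}

#' Read a GenBank flat file into a plastome record
#' @param path GenBank flat file
#' @param species_id overrides the LOCUS name
#' @return a [plastome_record()]
#' @export
read_genbank <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0) stop("malformed GenBank file (no LOCUS line): ", path)
  locus_fields <- strsplit(trimws(lines[locus[1]]), "\\s+")[[1]]
  if (is.null(species_id)) species_id <- locus_fields[2]

  f0 <- grep("^FEATURES", lines)
  o0 <- grep("^ORIGIN", lines)
  if (length(o0) == 0) stop("malformed GenBank file (no ORIGIN): ", path)
  seq_lines <- lines[(o0[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  genes <- list()
  if (length(f0) > 0) {
    feat_lines <- lines[(f0[1] + 1):(o0[1] - 1)]
    # fold continuation lines into single feature entries
    starts <- grep("^ {5}\\S", feat_lines)
    for (k in seq_along(starts)) {
      block <- feat_lines[starts[k]:(if (k < length(starts)) starts[k + 1] - 1
                                     else length(feat_lines))]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      loc <- sub("^ {5}\\S+\\s+", "", block[1])
      quals <- block[-1]
      # location may continue before the first qualifier
      qi <- grep("^\\s+/", quals)
      if (length(qi) == 0) qi <- length(quals) + 1L
      if (min(qi) > 1)
        loc <- paste0(loc, paste(trimws(quals[seq_len(min(qi) - 1)]), collapse = ""))
      quals <- trimws(quals)
      if (key == "source" || key == "gene") next
      if (!key %in% c("CDS", "tRNA", "rRNA")) {
        warning("ignoring feature of unknown class '", key, "' at line ",
                f0[1] + starts[k], call. = FALSE)
        next
      }
      gene_q <- grep('^/(gene|locus_tag|product)=', quals, value = TRUE)
      name <- if (length(gene_q) > 0)
        sub('^/[a-z_]+="?([^"]*)"?$', "\\1", gene_q[1]) else ""
      if (!nzchar(name)) {
        warning("feature ", key, " without a gene name skipped", call. = FALSE)
        next
      }
      parsed <- parse_gb_location(loc)
      if (is.null(parsed))
        stop("malformed location '", loc, "' for feature ", name, " in ", path)
      genes[[length(genes) + 1]] <-
        gene_annotation(name, key, parsed$strand, parsed$exons)
    }
  }
  plastome_record(species_id, sequence, genes)
}

# parse a GenBank location string; returns strand and 0-based half-open exons
parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|join|order", loc)) return(NULL)   # nested forms unsupported
  parts <- strsplit(loc, ",")[[1]]
  ex <- matrix(NA_integer_, length(parts), 2)
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else return(NULL)
    ex[i, ] <- c(ab[1] - 1L, ab[2])                        # to 0-based half-open
  }
  list(strand = strand, exons = ex)
}

#' Write a plastome record as a GenBank flat file
#' @param record a [plastome_record()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     record$species_id, n), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (g in record$genes) {
    iv <- sprintf("%d..%d", g$exons[, 1] + 1L, g$exons[, 2])
    loc <- if (length(iv) > 1) sprintf("join(%s)", paste(iv, collapse = ",")) else iv
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", g$feature_class, loc), con)
    writeLines(sprintf('                     /gene="%s"', g$name), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  for (off in seq(1, n, 60)) {
    chunk <- substr(s, off, min(off + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write a plastome as FASTA plus annotation TSV
#' @param record a [plastome_record()]
#' @param fasta output FASTA path
#' @param annotation output TSV path (default `<stem>.ann.tsv`)
#' @return `fasta`, invisibly
#' @export
write_plastome_fasta <- function(record, fasta,
                                 annotation = paste0(tools::file_path_sans_ext(fasta), ".ann.tsv")) {
  ss <- Biostrings::DNAStringSet(record$sequence)
  names(ss) <- record$species_id
  Biostrings::writeXStringSet(ss, fasta, width = 70)
  write_annotation_tsv(record$genes, annotation)
  invisible(fasta)
}

#' Read an annotation table
#'
#' Tab-separated columns: `gene`, `class`, `strand`, `exons` where `exons`
#' is a `;`-separated list of `start-end` intervals, 0-based half-open.
#'
#' @param path TSV path
#' @return list of [gene_annotation()]
#' @export
read_annotation_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    ivs <- strsplit(tab$exons[i], ";")[[1]]
    ex <- t(vapply(strsplit(ivs, "-"), function(p) as.integer(p), integer(2)))
    gene_annotation(tab$gene[i], tab$class[i], tab$strand[i], ex)
  })
}

#' Write an annotation table (see [read_annotation_tsv()] for the format)
#' @param genes list of [gene_annotation()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_annotation_tsv <- function(genes, path) {
  tab <- data.frame(
    gene = vapply(genes, `[[`, "", "name"),
    class = vapply(genes, `[[`, "", "feature_class"),
    strand = vapply(genes, `[[`, "", "strand"),
    exons = vapply(genes, function(g)
      paste(sprintf("%d-%d", g$exons[, 1], g$exons[, 2]), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
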