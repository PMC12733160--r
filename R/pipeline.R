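# End-to-end orchestration over a directory of plastomes, the default
# plastid gene -> functional category map, and per-category summaries.

#' Functional category of a plastid gene
#'
#' Maps standard plastid gene nomenclature to the eleven functional
#' categories used throughout the package: photosystem I (psa*),
#' photosystem II (psb*), cytochrome b6/f (pet*), ATP synthase (atp*),
#' NADH dehydrogenase (ndh*), RubisCO large subunit (rbcL), RNA polymerase
#' (rpo*), small ribosomal protein (rps*), large ribosomal protein (rpl*),
#' hypothetical reading frame (ycf*), and other.
#'
#' @param gene_name character vector of gene names
#' @param extra optional named character vector overriding or extending the
#'   default map (name -> category)
#' @return character vector of category labels
#' @export
plastid_gene_category <- function(gene_name, extra = NULL) {
  g <- tolower(gene_name)
  out <- rep("other", length(g))
  rules <- list(
    c("^psa", "photosystem I"), c("^psb", "photosystem II"),
    c("^pet", "cytochrome b6/f"), c("^atp", "ATP synthase"),
    c("^ndh", "NADH dehydrogenase"), c("^rbcl$", "RubisCO large subunit"),
    c("^rpo", "RNA polymerase"), c("^rps", "small ribosomal protein"),
    c("^rpl", "large ribosomal protein"),
    c("^ycf", "hypothetical reading frame (ycf)"))
  for (r in rules) out[grepl(r[1], g)] <- r[2]
  if (!is.null(extra)) {
    hit <- match(g, tolower(names(extra)))
    out[!is.na(hit)] <- unname(extra[hit[!is.na(hit)]])
  }
  out
}

#' The fixed functional category vocabulary
#' @return character vector of the 11 category labels
#' @export
gene_categories <- function() {
  c("photosystem I", "photosystem II", "cytochrome b6/f", "ATP synthase",
    "NADH dehydrogenase", "RubisCO large subunit", "RNA polymerase",
    "small ribosomal protein", "large ribosomal protein",
    "hypothetical reading frame (ycf)", "other")
}

#' Per-functional-category codon-usage and selection summary
#'
#' @param profile_table output of [codon_profile_table()]
#' @param pairs optional Ka/Ks pair table from [kaks_pairs()] to join mean
#'   ratios and positive-selection fractions
#' @return data frame, one row per category present
#' @export
category_summary <- function(profile_table, pairs = NULL) {
  profile_table$category[is.na(profile_table$category)] <- "other"
  sp <- split(profile_table, profile_table$category)
  rows <- lapply(sp, function(d) {
    data.frame(category = d$category[1], n_genes = nrow(d),
               mean_enc = mean(d$enc, na.rm = TRUE),
               sd_enc = sd(d$enc, na.rm = TRUE),
               mean_gc3 = mean(d$gc3, na.rm = TRUE),
               sd_gc3 = sd(d$gc3, na.rm = TRUE),
               mean_gc3s = mean(d$gc3s, na.rm = TRUE),
               mean_gc12 = mean(d$gc12, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    def <- pairs[!is.na(pairs$ratio), , drop = FALSE]
    kk <- split(def, def$category)
    out$mean_kaks <- vapply(out$category, function(cg)
      if (cg %in% names(kk)) mean(kk[[cg]]$ratio) else NA_real_, numeric(1))
    out$frac_positive <- vapply(out$category, function(cg)
      if (cg %in% names(kk)) mean(kk[[cg]]$selection == "positive") else NA_real_,
      numeric(1))
  }
  out[order(out$category), , drop = FALSE]
}

#' Run the full comparative pipeline over a set of plastomes
#'
#' Executes, per genome: quadripartite detection, CDS extraction and
#' curation, the codon-usage battery and correspondence analysis; across
#' genomes: SSR mining with context classification and motif clustering,
#' all-pairs NG86 Ka/Ks with the selection summary, pairwise gene-order
#' synteny against the first genome, and a neighbor-joining tree from the
#' concatenated shared CDS alignment.  One table per analysis is written to
#' `out_dir` together with a JSON manifest (parameters, per-stage status and
#' timings, file checksums).  Stage failures are recorded; independent
#' stages continue.
#'
#' @param paths character vector of plastome files (GenBank or FASTA), or a
#'   directory containing them
#' @param out_dir output directory (created if needed)
#' @param min_ir minimum inverted-repeat length for boundary detection
#' @param ssr_thresholds SSR copy thresholds (see [ssr_thresholds()])
#' @param max_ratio Ka/Ks outlier cap
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic)
#' @return the manifest, invisibly
#' @export
run_all <- function(paths, out_dir, min_ir = 1000,
                    ssr_thresholds = plastevo::ssr_thresholds(),
                    max_ratio = 10, seed = 1L) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(gb|gbk|genbank|fa|fasta|fna)$",
                        full.names = TRUE)
  }
  if (length(paths) == 0) stop("no input genomes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = list(min_ir = min_ir,
                                     ssr_thresholds = as.list(ssr_thresholds),
                                     max_ratio = max_ratio, seed = seed),
                   n_genomes = length(paths), stages = list(), files = list())
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      ok = res$ok, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      error = if (!res$ok) res$error else NULL)
    if (res$ok) res$value else NULL
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files[[file]] <<- unname(tools::md5sum(path))
  }

  records <- stage("parse", function() lapply(paths, parse_plastome))
  if (is.null(records)) stop("no genome could be parsed")

  stage("regions", function() {
    rows <- lapply(records, function(rec) {
      b <- tryCatch(detect_quadripartite(rec, min_ir), error = function(e) NULL)
      st <- region_stats(rec, boundaries = b)
      data.frame(species_id = rec$species_id, length = st$length,
                 lsc = if (is.null(b)) NA else st$region_lengths[["lsc"]],
                 ssc = if (is.null(b)) NA else st$region_lengths[["ssc"]],
                 ir = if (is.null(b)) NA else st$region_lengths[["ir"]],
                 gc_pct = st$gc_pct,
                 n_cds = st$gene_counts[["CDS"]], n_trna = st$gene_counts[["tRNA"]],
                 n_rrna = st$gene_counts[["rRNA"]], stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rows), "structure_summary.tsv")
  })

  cds_sets <- stage("cds", function() {
    sets <- lapply(records, extract_cds)
    rej <- do.call(rbind, lapply(seq_along(sets), function(i)
      if (nrow(sets[[i]]$rejected) > 0)
        cbind(species_id = records[[i]]$species_id, sets[[i]]$rejected) else NULL))
    if (!is.null(rej)) emit(rej, "cds_rejections.tsv")
    lapply(sets, `[[`, "genes")
  })
  all_genes <- if (is.null(cds_sets)) list() else unlist(cds_sets, recursive = FALSE)

  profiles <- stage("codon", function() {
    pt <- codon_profile_table(all_genes)
    emit(pt, "codon_profiles.tsv")
    emit(species_codon_summary(pt), "species_codon_summary.tsv")
    fits <- lapply(split(pt, pt$species_id), function(d)
      if (nrow(d) >= 2) {
        f <- neutrality_fit(d$gc12, d$gc3)
        data.frame(species_id = d$species_id[1], slope = f$slope,
                   intercept = f$intercept, r_squared = f$r_squared,
                   n_genes = f$n_genes)
      } else NULL)
    emit(do.call(rbind, fits), "neutrality_fits.tsv")
    pt
  })

  stage("coa", function() {
    per_species <- split(all_genes,
                         vapply(all_genes, `[[`, "", "species_id"))
    rows <- lapply(per_species, function(gs) {
      if (length(gs) < 3) return(NULL)
      res <- coa(rscu_matrix(gs), n_axes = 2)
      data.frame(species_id = gs[[1]]$species_id,
                 total_inertia = res$total_inertia,
                 axis1_pct = res$axis_pct[1],
                 axis2_pct = if (length(res$axis_pct) > 1) res$axis_pct[2] else NA,
                 stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rows), "coa_summary.tsv")
  })

  loci <- stage("ssr", function() {
    per <- lapply(records, function(rec)
      classify_context(find_ssrs(rec$sequence, ssr_thresholds,
                                 species_id = rec$species_id), rec))
    all_loci <- do.call(rbind, per)
    emit(all_loci, "ssr_loci.tsv")
    if (length(records) >= 2 && nrow(all_loci) > 0) {
      m <- motif_presence_matrix(all_loci)
      emit(data.frame(species_id = rownames(m), m, check.names = FALSE),
           "ssr_presence.tsv")
      cl <- cluster_species(m)
      writeLines(cl$newick, file.path(out_dir, "ssr_dendrogram.nwk"))
      manifest$files[["ssr_dendrogram.nwk"]] <<-
        unname(tools::md5sum(file.path(out_dir, "ssr_dendrogram.nwk")))
    }
    all_loci
  })

  pairs <- stage("kaks", function() {
    p <- kaks_pairs(all_genes)
    emit(p, "kaks_pairs.tsv")
    if (nrow(p) > 0 && any(!is.na(p$ratio))) {
      ss <- selection_summary(p, max_ratio = max_ratio)
      emit(ss$category_stats, "kaks_category_stats.tsv")
      emit(ss$pairwise_tests, "kaks_category_tests.tsv")
    }
    p
  })

  stage("category", function() {
    if (is.null(profiles)) stop("codon stage failed")
    emit(category_summary(profiles, pairs), "category_summary.tsv")
  })

  stage("synteny", function() {
    if (length(records) < 2) stop("need >= 2 genomes")
    rows <- lapply(records[-1], function(rec) {
      sy <- gene_order_synteny(records[[1]], rec)
      data.frame(species_a = records[[1]]$species_id, species_b = rec$species_id,
                 n_shared = sy$n_shared, n_blocks = sy$n_blocks,
                 breakpoints = sy$breakpoints,
                 collinear_fraction = sy$collinear_fraction,
                 stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rows), "synteny_report.tsv")
  })

  stage("tree", function() {
    if (length(records) < 3) stop("need >= 3 genomes")
    by_gene <- split(all_genes, tolower(vapply(all_genes, `[[`, "", "gene_name")))
    by_gene <- Filter(function(g) length(g) >= 2, by_gene)
    if (length(by_gene) == 0) stop("no shared genes")
    aligned <- lapply(by_gene, function(gs) {
      ref <- gs[[1]]
      out <- c(setNames(ref$cds, ref$species_id))
      for (g in gs[-1]) {
        al <- codon_align(ref, g)
        out[g$species_id] <- paste(al$codons_b, collapse = "")
        out[ref$species_id] <- paste(al$codons_a, collapse = "")
      }
      w <- max(nchar(out))
      vapply(out, function(s) paste0(s, strrep("-", w - nchar(s))), "")
    })
    names(aligned) <- names(by_gene)
    sm <- concat_alignment(aligned)
    dm <- jc_distance(sm$alignment)
    tr <- nj_tree(dm)
    writeLines(ape::write.tree(tr), file.path(out_dir, "nj_tree.nwk"))
    manifest$files[["nj_tree.nwk"]] <<-
      unname(tools::md5sum(file.path(out_dir, "nj_tree.nwk")))
    emit(sm$partitions, "tree_partitions.tsv")
    genus <- setNames(sub("[_ ].*$", "", tr$tip.label), tr$tip.label)
    emit(branch_rate_summary(tr, genus), "branch_rates.tsv")
  })

  manifest$n_failures <- sum(!vapply(manifest$stages, `[[`, TRUE, "ok"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
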