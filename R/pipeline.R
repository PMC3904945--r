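#' @title End-to-end pipeline
#'
#' @description
#' Orchestrates a full run over a directory of inputs: allele typing
#' from per-locus FASTA alignments and the amplification-call table,
#' panel assembly, frequency and genotype-distribution tables,
#' diversity statistics, NJ trees with bootstrap supports, the
#' population barrier matrix, and (optionally) pollen phenotype
#' summaries. Every output file carries a header comment with the run
#' seed and the md5 checksums of its inputs; reruns with the same seed
#' are byte-identical.
#'
#' @name pipeline
NULL

# write a data.frame as TSV with a provenance header
write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by the pipeline (skipping `#` header lines)
#'
#' @param path file path
#' @return data.frame
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

provenance <- function(seed, inputs) {
  sums <- vapply(inputs, function(p) unname(tools::md5sum(p)), "")
  c(sprintf("seed=%s", seed),
    sprintf("input %s md5=%s", basename(inputs), sums))
}

#' Run the full analysis pipeline
#'
#' @param config list with elements:
#'   \describe{
#'     \item{alignments}{named list locus -> FASTA path}
#'     \item{metadata}{TSV path with `accession`, `group` (and optional
#'       `diploid`) columns}
#'     \item{amp_calls}{optional TSV path (`accession`, `locus`,
#'       `primer_set`, `outcome`) for the SaFX complementary assay}
#'     \item{pollen}{optional TSV path (`accession`, `genotype`,
#'       `field`, `viable`, `nonviable`)}
#'     \item{out_dir}{output directory (created)}
#'     \item{bootstrap_B}{bootstrap replicates (default 100)}
#'     \item{seed}{integer seed (default 1)}
#'     \item{locus_config}{optional locus-definition override (path or
#'       list)}
#'   }
#' @return invisibly, a list of the artifact paths written and the
#'   in-memory results
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$metadata), !is.null(config$alignments))
  B <- config$bootstrap_B
  if (is.null(B)) B <- 100L
  if (B < 1L) stop("bootstrap_B must be >= 1")
  seed <- config$seed
  if (is.null(seed)) seed <- 1L
  inputs <- c(unlist(config$alignments), config$metadata,
              config$amp_calls, config$pollen)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop("input file(s) not found: ", paste(missing_in, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance(seed, inputs)
  defs <- load_locus_definitions(config$locus_config)

  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()
  log_lines <- c(hdr, sprintf("R=%s", getRversion()),
                 sprintf("bootstrap_B=%d", B))

  # --- typing ---------------------------------------------------------
  metadata <- stage("metadata", utils::read.delim(config$metadata,
                                                  stringsAsFactors = FALSE))
  safx_carriers <- character()
  amp <- NULL
  if (!is.null(config$amp_calls)) {
    amp <- utils::read.delim(config$amp_calls, stringsAsFactors = FALSE)
    by_acc <- split(amp, amp$accession)
    for (acc in names(by_acc)) {
      d <- by_acc[[acc]]
      saf <- d$outcome[d$primer_set == "SaF"][1]
      safdel <- d$outcome[d$primer_set == "SaFdel"][1]
      res <- detect_safx(if (is.na(saf)) NA_character_ else saf,
                         if (is.na(safdel)) NA_character_ else safdel)
      if (isTRUE(res$present)) safx_carriers <- c(safx_carriers, acc)
    }
  }

  calls_rows <- list()
  alns <- list()
  for (loc in names(config$alignments)) {
    aln <- stage(paste0("read:", loc),
                 read_alignment(config$alignments[[loc]]))
    alns[[loc]] <- aln
    calls <- stage(paste0("type:", loc),
                   type_alignment(defs[[loc]], aln, safx_carriers))
    calls_rows[[loc]] <- data.frame(
      accession = names(calls), locus = loc,
      allele = vapply(calls, `[[`, "", "allele_type"),
      missing = vapply(calls, `[[`, TRUE, "missing"),
      conflict = vapply(calls, `[[`, TRUE, "conflict"),
      stringsAsFactors = FALSE)
  }
  # SaFX carriers get SaF = SaFX calls even without sequence
  if (length(safx_carriers) && "SaF" %in% names(config$alignments)) {
    extra <- setdiff(safx_carriers, calls_rows[["SaF"]]$accession)
    if (length(extra)) {
      calls_rows[["SaF_del"]] <- data.frame(
        accession = extra, locus = "SaF", allele = "SaFX",
        missing = FALSE, conflict = FALSE, stringsAsFactors = FALSE)
    }
  }
  calls_df <- do.call(rbind, unname(calls_rows))
  rownames(calls_df) <- NULL
  paths$calls <- file.path(config$out_dir, "allele_calls.tsv")
  write_tsv_with_header(calls_df, paths$calls, hdr)

  # --- panel + tables -------------------------------------------------
  seq2acc <- calls_df
  panel <- stage("panel", build_panel(
    metadata, seq2acc[, c("accession", "locus", "allele")]))
  tab1 <- stage("freq-table", render_table1(
    panel, loci = intersect(names(allele_enumerations()),
                            unique(panel$locus))))
  paths$table1 <- file.path(config$out_dir, "allele_type_frequencies.tsv")
  write_tsv_with_header(tab1, paths$table1, hdr)

  dist_rows <- list()
  for (pair_nm in list(c("DPL1", "DPL2"), c("SaM", "SaF"))) {
    if (!all(pair_nm %in% unique(panel$locus))) next
    for (g in intersect(table1_group_order(), unique(panel$group))) {
      d <- genotype_distribution(panel, pair_nm, g)
      if (nrow(d)) {
        dist_rows[[paste(pair_nm[1], g)]] <-
          cbind(system = paste(pair_nm, collapse = "+"), group = g, d)
      }
    }
  }
  if (length(dist_rows)) {
    dist_df <- do.call(rbind, unname(dist_rows))
    rownames(dist_df) <- NULL
    paths$genotype_dist <- file.path(config$out_dir,
                                     "genotype_distributions.tsv")
    write_tsv_with_header(dist_df, paths$genotype_dist, hdr)
  }

  # --- diversity ------------------------------------------------------
  div_rows <- list()
  for (loc in names(alns)) {
    aln <- alns[[loc]]
    acc_groups <- setNames(metadata$group, metadata$accession)
    for (g in intersect(table1_group_order(), unique(metadata$group))) {
      members <- rownames(aln)[acc_groups[rownames(aln)] == g]
      members <- members[!is.na(members)]
      if (length(members) < 2L) next
      div_rows[[paste(loc, g)]] <- stage(
        paste0("diversity:", loc, ":", g),
        diversity_stats(aln[members, , drop = FALSE], group = g,
                        locus = loc))
    }
  }
  if (length(div_rows)) {
    div_df <- do.call(rbind, unname(div_rows))
    rownames(div_df) <- NULL
    fmt <- div_df
    fmt$tajima_d <- ifelse(is.na(div_df$tajima_d), "n/a",
                           sprintf("%.3f", div_df$tajima_d))
    fmt$pi <- sprintf("%.4f", div_df$pi)
    fmt$theta_w <- sprintf("%.4f", div_df$theta_w)
    paths$diversity <- file.path(config$out_dir, "diversity_stats.tsv")
    write_tsv_with_header(fmt, paths$diversity, hdr)
  }

  # --- trees ----------------------------------------------------------
  for (loc in names(alns)) {
    aln <- alns[[loc]]
    haps <- enumerate_haplotypes(aln)
    if (nrow(haps) < 4L) next
    hap_aln <- do.call(rbind, strsplit(haps$sequence, ""))
    rownames(hap_aln) <- paste0("hap", haps$haplotype_id)
    bt <- stage(paste0("tree:", loc),
                tryCatch(bootstrap_supports(hap_aln, B = B, seed = seed),
                         error = function(e) NULL))
    if (is.null(bt)) next
    p <- file.path(config$out_dir, paste0("tree_", loc, ".nwk"))
    con <- file(p, "w"); writeLines(paste0("# ", hdr), con); close(con)
    tmp <- tempfile(); write_support_newick(bt$tree, tmp)
    cat(readLines(tmp), file = p, sep = "\n", append = TRUE)
    paths[[paste0("tree_", loc)]] <- p
  }

  # --- barrier matrix -------------------------------------------------
  bm <- stage("barrier-matrix", population_barrier_matrix(panel))
  paths$barrier <- file.path(config$out_dir, "barrier_matrix.json")
  jsonlite::write_json(
    list(seed = seed, groups = rownames(bm),
         mean_fertility = as.data.frame(`attributes<-`(bm, list(dim = dim(bm), dimnames = dimnames(bm))))),
    paths$barrier, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- pollen (optional) ----------------------------------------------
  if (!is.null(config$pollen)) {
    pollen <- utils::read.delim(config$pollen, stringsAsFactors = FALSE)
    per_ind <- do.call(rbind, lapply(split(pollen, pollen$accession),
      function(d) data.frame(accession = d$accession[1],
                             genotype = d$genotype[1],
                             value = nonviable_percent(d),
                             stringsAsFactors = FALSE)))
    raw <- data.frame(accession = pollen$accession,
                      genotype = pollen$genotype,
                      value = 100 * pollen$nonviable /
                        (pollen$viable + pollen$nonviable))
    summ <- genotype_summary(raw)
    summ$mean_sd <- sprintf("%.1f (%.1f)", summ$mean, summ$sd)
    paths$pollen <- file.path(config$out_dir, "pollen_summary.tsv")
    write_tsv_with_header(summ, paths$pollen, hdr)
  } else {
    log_lines <- c(log_lines, "pollen inputs absent: phenotype outputs skipped")
  }

  paths$log <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)
  invisible(list(paths = paths, panel = panel, calls = calls_df))
}
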