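#' Build a genotype panel from sample metadata and allele calls
#'
#' Assembles per-accession genotype records in long form: one row per
#' allele copy (so a diploid wild accession typed at a locus contributes
#' two rows, a haploid/inbred accession one, and rare heterozygous
#' cultivated accessions two). Missing calls (amplification failures)
#' are preserved with `allele = NA` so they can be tallied but excluded
#' from frequency denominators.
#'
#' @param metadata data.frame with columns `accession` and `group`
#'   (groups from [oryza_groups()]); an optional logical `diploid`
#'   column marks accessions whose loci carry two alleles (defaults to
#'   `TRUE` for the wild group, `FALSE` elsewhere)
#' @param calls data.frame with columns `accession`, `locus`, `allele`
#'   (allele-type label or `NA` for a missing call); one row per allele
#'   copy
#' @return data.frame of class `hi_panel` with columns `accession`,
#'   `group`, `diploid`, `locus`, `allele`
#' @export
build_panel <- function(metadata, calls) {
  stopifnot(all(c("accession", "group") %in% names(metadata)),
            all(c("accession", "locus", "allele") %in% names(calls)))
  if (anyDuplicated(metadata$accession)) {
    stop("duplicate accession ids in metadata: ",
         paste(unique(metadata$accession[duplicated(metadata$accession)]),
               collapse = ", "))
  }
  bad_grp <- setdiff(unique(metadata$group), oryza_groups())
  if (length(bad_grp)) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  }
  orphan <- setdiff(unique(calls$accession), metadata$accession)
  if (length(orphan)) {
    stop("calls reference accession(s) absent from metadata: ",
         paste(orphan, collapse = ", "))
  }
  enums <- allele_enumerations()
  bad_locus <- setdiff(unique(calls$locus), names(enums))
  if (length(bad_locus)) {
    stop("unknown locus in calls: ", paste(bad_locus, collapse = ", "))
  }
  for (loc in unique(calls$locus)) {
    al <- calls$allele[calls$locus == loc]
    bad <- setdiff(al[!is.na(al)], enums[[loc]])
    if (length(bad)) {
      stop("allele label(s) not in the ", loc, " enumeration: ",
           paste(bad, collapse = ", "))
    }
  }
  if (!"diploid" %in% names(metadata)) {
    metadata$diploid <- metadata$group == "wild"
  }
  panel <- merge(calls, metadata[, c("accession", "group", "diploid")],
                 by = "accession", sort = FALSE)
  panel <- panel[, c("accession", "group", "diploid", "locus", "allele")]
  class(panel) <- c("hi_panel", "data.frame")
  panel
}

#' Allele-type frequencies for one locus in one population
#'
#' Computes the table-style frequency row: integer percentages
#' (round-half-up) of each allele type over non-missing alleles, with
#' the exact percentage kept alongside. For \emph{s5} the indica-type
#' share pools \code{s5-i} and \code{s5-n} (the wide-compatibility
#' deletion arises on indica-type backgrounds), and `wc_percent` gives
#' the share of indica-type alleles carrying the deletion — the "wc"
#' row convention, computed out of total indica-type alleles only.
#'
#' @param panel an `hi_panel` from [build_panel()]
#' @param locus locus name
#' @param group population label
#' @return data.frame with one row per allele type (`count`, `n`,
#'   `percent_raw`, `percent`) and attributes `n_alleles` (non-missing
#'   denominator), `n_missing`, and for s5 `wc_percent`/`wc_percent_raw`
#'   (`NA` when no indica-type alleles); zero denominator returns an
#'   explicit empty row set (attribute `n_alleles` = 0), not zeros
#' @export
allele_type_frequencies <- function(panel, locus, group) {
  enums <- allele_enumerations()
  stopifnot(locus %in% names(enums))
  rows <- panel[panel$locus == locus & panel$group == group, ]
  alleles <- rows$allele
  n_missing <- sum(is.na(alleles))
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)

  types <- enums[[locus]]
  if (n == 0L) {
    out <- data.frame(locus = character(), group = character(),
                      allele_type = character(), count = integer(),
                      n = integer(), percent_raw = numeric(),
                      percent = integer(), stringsAsFactors = FALSE)
    attr(out, "n_alleles") <- 0L
    attr(out, "n_missing") <- n_missing
    return(out)
  }
  counts <- vapply(types, function(t) sum(alleles == t), integer(1))
  pct <- lapply(counts, percent_of, n = n)
  out <- data.frame(locus = locus, group = group, allele_type = types,
                    count = unname(counts), n = n,
                    percent_raw = vapply(pct, `[[`, numeric(1), "raw"),
                    percent = vapply(pct, `[[`, numeric(1), "percent"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_alleles") <- n
  attr(out, "n_missing") <- n_missing
  if (locus == "s5") {
    n_ind <- sum(alleles %in% c("s5-i", "s5-n"))
    n_wc <- sum(alleles == "s5-n")
    if (n_ind > 0L) {
      p <- percent_of(n_wc, n_ind)
      attr(out, "wc_percent_raw") <- p$raw
      attr(out, "wc_percent") <- p$percent
      p2 <- percent_of(n_ind, n)
      attr(out, "indica_type_percent_raw") <- p2$raw
      attr(out, "indica_type_percent") <- p2$percent
    } else {
      attr(out, "wc_percent_raw") <- NA_real_
      attr(out, "wc_percent") <- NA_integer_
      attr(out, "indica_type_percent_raw") <- 0
      attr(out, "indica_type_percent") <- 0L
    }
  }
  out
}

#' Joint genotype distribution for a two-gene system
#'
#' Tallies the joint haploid genotypes (e.g. `DPL1-N+/DPL2-K+`) for a
#' two-locus system within one population. Individuals heterozygous at
#' either locus are written out as full diploid genotypes
#' (`a1/a2//b1/b2`). Individuals missing a call at either locus are
#' excluded and counted in the `excluded` attribute.
#'
#' @param panel an `hi_panel`
#' @param locus_pair character length-2, `c("DPL1","DPL2")` or
#'   `c("SaM","SaF")`
#' @param group population label
#' @return data.frame with `genotype`, `count`, `percent_raw`,
#'   `percent`; attribute `excluded` counts individuals dropped for a
#'   missing locus
#' @export
genotype_distribution <- function(panel, locus_pair, group) {
  stopifnot(length(locus_pair) == 2L)
  rows <- panel[panel$group == group & panel$locus %in% locus_pair, ]
  accs <- unique(rows$accession)
  labels <- character()
  excluded <- 0L
  for (acc in accs) {
    a <- rows$allele[rows$accession == acc & rows$locus == locus_pair[1]]
    b <- rows$allele[rows$accession == acc & rows$locus == locus_pair[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) {
      excluded <- excluded + 1L
      next
    }
    if (length(unique(a)) == 1L && length(unique(b)) == 1L) {
      labels <- c(labels, paste0(a[1], "/", b[1]))
    } else {
      labels <- c(labels,
                  paste0(paste(sort(unique(a)), collapse = "/"), "//",
                         paste(sort(unique(b)), collapse = "/")))
    }
  }
  if (length(labels) == 0L) {
    out <- data.frame(genotype = character(), count = integer(),
                      percent_raw = numeric(), percent = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }
  tab <- table(labels)
  tab <- tab[order(-tab, names(tab))]
  pct <- lapply(as.integer(tab), percent_of, n = length(labels))
  out <- data.frame(genotype = names(tab), count = as.integer(tab),
                    percent_raw = vapply(pct, `[[`, numeric(1), "raw"),
                    percent = vapply(pct, `[[`, numeric(1), "percent"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Render the population-by-locus allele-type frequency table
#'
#' Lays out frequency rows in the fixed population column order
#' (indica, aus, japonica, SH, BHA1, BHA2, MX, BRH, wild), one block of
#' rows per locus plus an "alleles sampled" row; the s5 block carries a
#' "wc" row (percent of indica-type alleles with the wide-compatibility
#' deletion) and its s5-i row reports the pooled indica-type share.
#' Populations without data appear as empty columns, not omitted.
#'
#' @param panel an `hi_panel`
#' @param loci loci to include (default all five)
#' @return data.frame with columns `locus`, `row` and one column per
#'   population (integer percentages as character; "" when no data)
#' @export
render_table1 <- function(panel, loci = names(allele_enumerations())) {
  groups <- table1_group_order()
  enums <- allele_enumerations()
  blocks <- list()
  for (loc in loci) {
    row_names <- if (loc == "s5") {
      c("s5-i", "wc", "s5-j")
    } else {
      enums[[loc]]
    }
    cells <- matrix("", nrow = length(row_names) + 1L, ncol = length(groups),
                    dimnames = list(c(row_names, "alleles sampled"), groups))
    for (g in groups) {
      fr <- allele_type_frequencies(panel, loc, g)
      n <- attr(fr, "n_alleles")
      if (n == 0L) next
      if (loc == "s5") {
        cells["s5-i", g] <- as.character(attr(fr, "indica_type_percent"))
        wc <- attr(fr, "wc_percent")
        cells["wc", g] <- if (is.na(wc)) "0" else as.character(wc)
        cells["s5-j", g] <- as.character(fr$percent[fr$allele_type == "s5-j"])
      } else {
        for (t in enums[[loc]]) {
          cells[t, g] <- as.character(fr$percent[fr$allele_type == t])
        }
      }
      cells["alleles sampled", g] <- as.character(n)
    }
    blocks[[loc]] <- data.frame(locus = loc, row = rownames(cells),
                                cells, stringsAsFactors = FALSE,
                                row.names = NULL, check.names = FALSE)
  }
  do.call(rbind, blocks)
}
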