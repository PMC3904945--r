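#' @title Locus models for the rice hybrid-incompatibility genes
#'
#' @description
#' Five loci make up the three cloned hybrid sterility systems of Asian
#' rice: \emph{s5} (chromosome 6, embryo-sac system), the duplicate pair
#' \emph{DPL1}/\emph{DPL2} (chromosomes 1 and 6, pollen system) and the
#' adjacent genes \emph{SaM}/\emph{SaF} (chromosome 1, pollen system).
#' Each is typed from a small set of diagnostic polymorphisms:
#' \itemize{
#'   \item \emph{s5}: two SNPs (published CDS symbols C282A and C877T)
#'     separate the indica (\code{s5-i}) and japonica (\code{s5-j})
#'     alleles; a 136-bp deletion defines the non-functional
#'     wide-compatibility allele \code{s5-n}.
#'   \item \emph{DPL1}: a 517-bp insertion 204 bp downstream of the start
#'     codon defines the non-functional \code{DPL1-K-}; its absence the
#'     functional \code{DPL1-N+}.
#'   \item \emph{DPL2}: the SNP A434G separates functional \code{DPL2-K+}
#'     (A) from non-functional \code{DPL2-N-} (G).
#'   \item \emph{SaM}: a G-to-T SNP in the fifth intron separates
#'     \code{SaM+} (G, indica) from \code{SaM-} (T, japonica; truncated
#'     protein).
#'   \item \emph{SaF}: a C-to-T transition (published position 287)
#'     separates \code{SaF+} (C) from \code{SaF-} (T); the 8,628-bp
#'     \code{SaFX} deletion removes the whole gene plus the first four
#'     exons (1,240 bp) of \emph{SaM}, so SaM alleles in SaFX carriers
#'     are re-assigned \code{SaM+X}/\code{SaM-X}.
#' }
#' Published SNP symbols are coding-sequence positions from the original
#' cloning studies; operationally every diagnostic is addressed by an
#' alignment column in the locus definition, with the CDS symbol kept as
#' an annotation, and the indica/japonica state convention is part of the
#' (overridable) configuration.
#'
#' @name locus_models
NULL

#' Allele-type enumerations per locus
#'
#' @return named list: locus name -> character vector of valid
#'   allele-type labels
#' @export
allele_enumerations <- function() {
  list(
    s5   = c("s5-i", "s5-j", "s5-n"),
    DPL1 = c("DPL1-N+", "DPL1-K-"),
    DPL2 = c("DPL2-K+", "DPL2-N-"),
    SaM  = c("SaM+", "SaM-", "SaM+X", "SaM-X"),
    SaF  = c("SaF+", "SaF-", "SaFX")
  )
}

# Built-in locus definitions. Alignment lengths follow the sequenced
# amplicons (s5 1897 bp, DPL2 499 bp, SaM 634 bp, SaF ~1.3 kb); DPL1 is
# assayed by insertion presence, its alignment length includes the
# 517-bp insertion block. Diagnostic columns are configuration choices
# within each amplicon (CDS-frame symbols kept as annotation).
builtin_locus_definitions <- function() {
  list(
    s5 = list(
      name = "s5", chromosome = "6",
      amplicon_span = "1897 bp from 949 bp downstream of the start codon (exon 2) to 1016 bp past the stop codon",
      length = 1897L,
      diagnostics = list(
        list(kind = "SNP", name = "C282A", position = 1200L,
             ref_state = "C", alt_state = "A",
             state_labels = c(C = "j", A = "i")),
        list(kind = "SNP", name = "C877T", position = 1500L,
             ref_state = "C", alt_state = "T",
             state_labels = c(C = "j", T = "i"))
      ),
      deletion_defs = list(
        list(name = "s5-n", length = 136L, start = 50L, end = 186L,
             detection_mode = "sequence-gap",
             collateral = "N-terminal coding sequence; renders s5 non-functional")
      ),
      type_map = c(i = "s5-i", j = "s5-j"),
      deletion_types = c("s5-n" = "s5-n")
    ),
    DPL1 = list(
      name = "DPL1", chromosome = "1",
      amplicon_span = "region spanning the 517-bp insertion 204 bp downstream of the start codon",
      length = 1200L,
      diagnostics = list(
        list(kind = "indel", name = "ins517", position = 300L,
             indel_length = 517L,
             ref_state = "absent", alt_state = "present",
             state_labels = c(absent = "N", present = "K"))
      ),
      deletion_defs = list(),
      type_map = c(N = "DPL1-N+", K = "DPL1-K-"),
      deletion_types = character()
    ),
    DPL2 = list(
      name = "DPL2", chromosome = "6",
      amplicon_span = "499 bp from 16 bp into exon 1 through 19 bp into exon 2",
      length = 499L,
      diagnostics = list(
        list(kind = "SNP", name = "A434G", position = 210L,
             ref_state = "A", alt_state = "G",
             state_labels = c(A = "i", G = "j"))
      ),
      deletion_defs = list(),
      type_map = c(i = "DPL2-K+", j = "DPL2-N-"),
      deletion_types = character()
    ),
    SaM = list(
      name = "SaM", chromosome = "1",
      amplicon_span = "634 bp from 4 bp into exon 4 through 44 bp downstream of exon 5",
      length = 634L,
      diagnostics = list(
        list(kind = "SNP", name = "intron5_G_T", position = 420L,
             ref_state = "G", alt_state = "T",
             state_labels = c(G = "i", T = "j"))
      ),
      deletion_defs = list(
        list(name = "SaFX", length = 8628L,
             start = 22371187L, end = 22379815L,
             detection_mode = "complementary-primer-amplification",
             collateral = "all of SaF, part of Os01g39660, first four exons (1,240 bp) of SaM")
      ),
      type_map = c(i = "SaM+", j = "SaM-"),
      deletion_types = c(SaFX = "X-suffix")
    ),
    SaF = list(
      name = "SaF", chromosome = "1",
      amplicon_span = "1.3 kb from 674 bp into exon 1 through 357 bp into exon 3",
      length = 1300L,
      diagnostics = list(
        list(kind = "SNP", name = "C287T", position = 500L,
             ref_state = "C", alt_state = "T",
             state_labels = c(C = "i", T = "j"))
      ),
      deletion_defs = list(
        list(name = "SaFX", length = 8628L,
             start = 22371187L, end = 22379815L,
             detection_mode = "complementary-primer-amplification",
             collateral = "all of SaF, part of Os01g39660, first four exons (1,240 bp) of SaM")
      ),
      type_map = c(i = "SaF+", j = "SaF-"),
      deletion_types = c(SaFX = "SaFX")
    )
  )
}

validate_locus_definition <- function(def) {
  known <- names(allele_enumerations())
  if (!def$name %in% known) {
    stop("unknown locus name '", def$name, "' (known loci: ",
         paste(known, collapse = ", "), ")")
  }
  if (length(def$diagnostics) + length(def$deletion_defs) < 1L) {
    stop("locus '", def$name, "' has no diagnostics or deletion definitions")
  }
  pos <- vapply(def$diagnostics, function(d) d$position, integer(1))
  if (anyDuplicated(pos)) {
    stop("locus '", def$name, "' has overlapping diagnostics at position ",
         pos[duplicated(pos)][1])
  }
  for (d in def$diagnostics) {
    if (identical(d$ref_state, d$alt_state)) {
      stop("diagnostic '", d$name, "' has identical ref and alt states")
    }
    if (d$position < 1L || d$position > def$length) {
      stop("diagnostic '", d$name, "' lies outside the '", def$name,
           "' amplicon (position ", d$position, ", length ", def$length, ")")
    }
  }
  for (dd in def$deletion_defs) {
    if (!is.null(dd$start) && !is.null(dd$end) &&
        dd$end - dd$start != dd$length) {
      stop("deletion '", dd$name, "': end - start (", dd$end - dd$start,
           ") does not equal length (", dd$length, ")")
    }
  }
  invisible(def)
}

#' Load locus definitions
#'
#' Returns the five built-in locus definitions, optionally overridden by
#' a user configuration (a JSON file or an equivalent list) that may move
#' diagnostic columns or change state conventions. Unknown locus names
#' and inconsistent definitions are rejected.
#'
#' @param config `NULL` (built-ins), a path to a JSON config, or a list
#'   with per-locus blocks of the same shape as the built-ins
#' @return named list of locus definitions (class `locus_definition`)
#' @export
load_locus_definitions <- function(config = NULL) {
  defs <- builtin_locus_definitions()
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      config <- jsonlite::read_json(config, simplifyVector = FALSE)
    }
    if (!is.list(config)) stop("config must be a list or a JSON file path")
    for (nm in names(config)) {
      if (!nm %in% names(defs)) {
        stop("unknown locus name '", nm, "' in config")
      }
      blk <- config[[nm]]
      for (fld in names(blk)) defs[[nm]][[fld]] <- blk[[fld]]
    }
  }
  for (nm in names(defs)) {
    defs[[nm]] <- validate_locus_definition(defs[[nm]])
    class(defs[[nm]]) <- c("locus_definition", "list")
  }
  defs
}

new_allele_call <- function(locus, allele_type = NA_character_,
                            evidence = NULL, missing = FALSE,
                            conflict = FALSE, note = NA_character_) {
  structure(
    list(locus = locus, allele_type = allele_type, evidence = evidence,
         missing = missing, conflict = conflict, note = note),
    class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  lab <- if (x$conflict) "<conflict>" else if (x$missing) "<missing>" else x$allele_type
  cat(sprintf("%s allele call: %s\n", x$locus, lab))
  invisible(x)
}

#' Classify an observed diagnostic-state vector into an allele type
#'
#' Pure, deterministic mapping from observed diagnostic states and
#' deletion flags to the locus's allele-type enumeration. Deletion
#' evidence takes precedence over SNP states (the 136-bp deletion makes
#' \code{s5-n} regardless of the s5 SNPs; the SaFX deletion makes
#' \code{SaFX} at SaF and appends the X suffix at SaM). An \code{N} or
#' gap at a diagnostic yields a missing call unless the remaining
#' diagnostics are decisive on their own; diagnostics that disagree
#' (e.g. a recombinant s5 haplotype) are surfaced as a conflict, never
#' silently resolved.
#'
#' @param locus_def a locus definition from [load_locus_definitions()]
#' @param observed list with `states` (named character vector over the
#'   locus's diagnostics; SNP values in ref/alt/`"-"`/`"N"`/`NA`, indel
#'   diagnostics in `"present"`/`"absent"`/`NA`), optional `deletions`
#'   (named logical over deletion definitions, `NA` = unknown) and
#'   optional `conflict` (logical, upstream assay conflict)
#' @return an `allele_call` with fields `locus`, `allele_type`,
#'   `evidence`, `missing`, `conflict`
#' @export
classify_allele <- function(locus_def, observed) {
  stopifnot(inherits(locus_def, "locus_definition"))
  states <- observed$states %||% character()
  dels <- observed$deletions %||% logical()

  if (isTRUE(observed$conflict)) {
    return(new_allele_call(locus_def$name, NA_character_, observed,
                           missing = TRUE, conflict = TRUE,
                           note = "conflicting assay evidence"))
  }

  # validate states
  for (d in locus_def$diagnostics) {
    s <- lookup(states, d$name, NA_character_)
    allowed <- c(d$ref_state, d$alt_state, "-", "N")
    if (!is.na(s) && !s %in% allowed) {
      stop("state '", s, "' at diagnostic '", d$name,
           "' is outside {ref, alt, gap, N}")
    }
  }

  # deletion precedence
  if (length(locus_def$deletion_defs)) {
    for (dd in locus_def$deletion_defs) {
      flag <- lookup(dels, dd$name, NA)
      if (isTRUE(flag)) {
        mode <- locus_def$deletion_types[[dd$name]]
        if (identical(mode, "X-suffix")) {
          # SaM in a SaFX carrier: base type from the surviving SNP
          tag <- snp_tags(locus_def, states)
          if (length(tag$tags) == 0L) {
            return(new_allele_call(locus_def$name, NA_character_, observed,
                                   missing = TRUE,
                                   note = "SaFX carrier with unreadable SaM SNP"))
          }
          if (tag$conflict) {
            return(new_allele_call(locus_def$name, NA_character_, observed,
                                   missing = TRUE, conflict = TRUE,
                                   note = "diagnostics disagree"))
          }
          base <- unname(locus_def$type_map[[tag$tags[1]]])
          return(new_allele_call(locus_def$name, paste0(base, "X"), observed))
        }
        return(new_allele_call(locus_def$name, unname(mode), observed))
      }
    }
  }

  tag <- snp_tags(locus_def, states)
  if (tag$conflict) {
    return(new_allele_call(locus_def$name, NA_character_, observed,
                           missing = TRUE, conflict = TRUE,
                           note = "diagnostics disagree (possible recombinant)"))
  }
  if (length(tag$tags) == 0L) {
    return(new_allele_call(locus_def$name, NA_character_, observed,
                           missing = TRUE, note = "no readable diagnostic"))
  }
  new_allele_call(locus_def$name, unname(locus_def$type_map[[tag$tags[1]]]),
                  observed)
}

# Collect type tags from readable diagnostics; missing states are dropped
# (remaining states decide when they agree).
snp_tags <- function(locus_def, states) {
  tags <- character()
  for (d in locus_def$diagnostics) {
    s <- lookup(states, d$name, NA_character_)
    if (is.na(s) || s %in% c("-", "N")) next
    tags <- c(tags, unname(d$state_labels[[s]]))
  }
  list(tags = unique(tags), conflict = length(unique(tags)) > 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Safe named lookup returning `default` when the name is absent.
lookup <- function(v, nm, default) {
  if (!is.null(names(v)) && nm %in% names(v)) v[[nm]] else default
}

#' Detect the SaFX deletion from the complementary primer assay
#'
#' The SaFX deletion is genotyped with two complementary primer sets:
#' the SaF primers amplify only when the deletion is absent, the SaFdel
#' primers only when it is present. Supplying the genomic breakpoint
#' coordinates (1-based, end-exclusive) also returns the deletion span.
#'
#' @param saf outcome of the SaF primers: `"success"`, `"fail"` or `NA`
#' @param safdel outcome of the SaFdel primers: `"success"`, `"fail"` or `NA`
#' @param breakpoints optional numeric length-2 `(start, end)` genomic
#'   coordinates, end-exclusive
#' @return list with `status` (`"present"`, `"absent"` or `"missing"`),
#'   `present` (logical, `NA` when missing) and `span_bp` (deletion
#'   length when breakpoints given, else `NA`)
#' @export
detect_safx <- function(saf = NA_character_, safdel = NA_character_,
                        breakpoints = NULL) {
  chk <- function(x) is.na(x) || x %in% c("success", "fail")
  if (!chk(saf) || !chk(safdel)) {
    stop("primer outcomes must be 'success', 'fail' or NA")
  }
  span <- NA_real_
  if (!is.null(breakpoints)) {
    stopifnot(length(breakpoints) == 2L, breakpoints[2] > breakpoints[1])
    span <- as.numeric(breakpoints[2] - breakpoints[1])
  }
  if (is.na(saf) && is.na(safdel) && is.null(breakpoints)) {
    stop("at least one primer outcome or breakpoint pair is required")
  }
  if (identical(saf, "success") && identical(safdel, "success")) {
    stop("conflicting assay: both SaF and SaFdel primers amplified")
  }
  status <- if (identical(saf, "success")) {
    "absent"
  } else if (identical(safdel, "success")) {
    "present"
  } else if (identical(saf, "fail") && identical(safdel, "fail")) {
    "missing"   # unexplained double failure; neither allele callable
  } else if (!is.null(breakpoints) && is.na(saf) && is.na(safdel)) {
    "present"
  } else {
    "missing"
  }
  list(status = status,
       present = if (status == "missing") NA else status == "present",
       span_bp = span)
}

#' Collapse an alignment into haplotypes
#'
#' Identical aligned strings (indel characters included) collapse to one
#' haplotype. The reference sequence, when named, receives haplotype id
#' 1 (the convention of numbering the sequenced-genome accession first);
#' remaining ids are assigned by descending allele count, ties broken by
#' first appearance in input order.
#'
#' @param aln alignment (see [as_alignment()])
#' @param reference_id rowname of the reference sequence, or `NULL`
#' @return data.frame with `haplotype_id`, `count`, `sequence` and a
#'   list-column `members`; counts sum to the number of input sequences
#' @export
enumerate_haplotypes <- function(aln, reference_id = NULL) {
  aln <- as_alignment(aln)
  seqs <- apply(aln, 1, paste0, collapse = "")
  uniq <- unique(seqs)
  counts <- vapply(uniq, function(u) sum(seqs == u), integer(1))
  first <- vapply(uniq, function(u) which(seqs == u)[1], integer(1))
  ord <- order(-counts, first)
  uniq <- uniq[ord]; counts <- counts[ord]

  if (!is.null(reference_id)) {
    if (!reference_id %in% rownames(aln)) {
      stop("reference sequence '", reference_id, "' not in alignment")
    }
    ref_seq <- seqs[[reference_id]]
    i <- which(uniq == ref_seq)
    uniq <- c(uniq[i], uniq[-i])
    counts <- c(counts[i], counts[-i])
  }
  members <- lapply(uniq, function(u) names(seqs)[seqs == u])
  data.frame(haplotype_id = seq_along(uniq),
             count = unname(counts),
             sequence = unname(uniq),
             members = I(unname(members)),
             stringsAsFactors = FALSE)
}

#' Extract observed diagnostic states from an aligned sequence
#'
#' Bridges alignments and [classify_allele()]: reads each SNP
#' diagnostic's column, scores indel diagnostics and sequence-gap
#' deletion definitions from gap runs, and attaches externally supplied
#' deletion flags (e.g. SaFX primer results, which are not visible in
#' the SaM alignment).
#'
#' @param locus_def locus definition
#' @param seq_chars character vector (one alignment row)
#' @param external_deletions named logical of assay-derived deletion flags
#' @return `observed` list suitable for [classify_allele()]
#' @export
observe_sequence <- function(locus_def, seq_chars,
                             external_deletions = logical()) {
  states <- character()
  for (d in locus_def$diagnostics) {
    if (d$kind == "SNP") {
      states[[d$name]] <- seq_chars[[d$position]]
    } else {
      block <- seq_chars[d$position:(d$position + d$indel_length - 1L)]
      states[[d$name]] <- if (all(block == "-")) {
        "absent"
      } else if (!any(block == "-")) {
        "present"
      } else NA_character_
    }
  }
  dels <- logical()
  conflict <- FALSE
  for (dd in locus_def$deletion_defs) {
    if (identical(dd$detection_mode, "sequence-gap")) {
      block <- seq_chars[dd$start:(dd$end - 1L)]
      gap_call <- if (all(block == "-")) TRUE else if (!any(block == "-")) FALSE else NA
      ext <- lookup(external_deletions, dd$name, NA)
      if (!is.na(gap_call) && !is.na(ext) && gap_call != ext) conflict <- TRUE
      dels[[dd$name]] <- if (!is.na(gap_call)) gap_call else ext
    } else {
      dels[[dd$name]] <- lookup(external_deletions, dd$name, NA)
    }
  }
  list(states = states, deletions = dels, conflict = conflict)
}

#' Type every sequence in a locus alignment
#'
#' @param locus_def locus definition
#' @param aln alignment whose rownames are accession/sequence ids
#' @param safx_carriers character vector of ids known (from the primer
#'   assay) to carry the SaFX deletion
#' @return named list of `allele_call`s, one per row
#' @export
type_alignment <- function(locus_def, aln, safx_carriers = character()) {
  aln <- as_alignment(aln)
  out <- lapply(rownames(aln), function(id) {
    ext <- logical()
    if (length(locus_def$deletion_defs)) {
      for (dd in locus_def$deletion_defs) {
        if (identical(dd$detection_mode, "complementary-primer-amplification")) {
          ext[[dd$name]] <- id %in% safx_carriers
        }
      }
    }
    classify_allele(locus_def, observe_sequence(locus_def, aln[id, ], ext))
  })
  names(out) <- rownames(aln)
  out
}
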