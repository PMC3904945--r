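#' @title Synthetic aligned panels with ground truth
#'
#' @description
#' Generators for every fixture the pipeline consumes: locus alignments
#' whose sequences carry diagnostic states consistent with a chosen
#' allele-type composition (including the 136-bp s5 deletion, the
#' 517-bp DPL1 insertion, and SaFX as whole-amplicon absence with
#' complementary-primer records), genotype panels reproducing
#' table-style marginal counts, and noisy triplicate pollen
#' measurements. All generators are deterministic under their seed and
#' return the generating truth alongside the data. Neutral variation is
#' placed only at non-diagnostic columns, so truth labels can never be
#' corrupted; missing calls are simulated as whole-locus amplification
#' failures, the failure mode seen in practice.
#'
#' @name synthetic_data
NULL

# Columns that must not receive neutral variation or extra indels.
# Gap-block definitions are padded by three columns on each side so an
# extra indel run can never merge with them into one longer run.
reserved_columns <- function(locus_def) {
  cols <- integer()
  for (d in locus_def$diagnostics) {
    if (d$kind == "SNP") {
      cols <- c(cols, d$position)
    } else {
      cols <- c(cols, (d$position - 3L):(d$position + d$indel_length + 2L))
    }
  }
  for (dd in locus_def$deletion_defs) {
    if (identical(dd$detection_mode, "sequence-gap")) {
      cols <- c(cols, (dd$start - 3L):(dd$end + 2L))
    }
  }
  cols <- cols[cols >= 1L & cols <= locus_def$length]
  sort(unique(cols))
}

# nucleotide state realising a type tag at a SNP diagnostic
state_for_tag <- function(diag, tag) {
  names(diag$state_labels)[match(tag, diag$state_labels)]
}

#' Generate a locus alignment with known allele types
#'
#' Builds an aligned haplotype panel in which every sequence's
#' diagnostic states match its truth allele type. SaFX alleles (whole
#' amplicon deleted) contribute no FASTA sequence; they appear in the
#' truth table and as complementary-primer amplification records.
#'
#' @param locus locus name
#' @param type_counts named integer vector: allele-type label -> number
#'   of sequences (labels from the locus enumeration)
#' @param seed integer seed (mandatory for reproducibility)
#' @param target_S total number of segregating sites, counting any
#'   diagnostic SNP columns that segregate in the requested mix;
#'   neutral sites are placed at non-diagnostic columns to make up the
#'   difference (exact)
#' @param n_indels number of extra shared 3-bp indel events
#' @param n_haplotypes optional total distinct-haplotype target;
#'   private mutations are added to duplicate sequences until reached
#' @param locus_defs locus definitions (default built-ins)
#' @param missing_rate fraction of sequences replaced by whole-locus
#'   amplification failures (removed from the FASTA, truth kept with
#'   `missing = TRUE`)
#' @return list with `alignment` (character matrix; absent for loci
#'   where every allele is a whole-gene deletion), `truth` (data.frame
#'   `seq_id`, `allele_type`, `missing`), `amp_calls` (data.frame
#'   `accession`, `locus`, `primer_set`, `outcome`) and
#'   `safx_carriers`
#' @export
generate_alignment <- function(locus, type_counts, seed,
                               target_S = 0L, n_indels = 0L,
                               n_haplotypes = NULL,
                               locus_defs = load_locus_definitions(),
                               missing_rate = 0) {
  stopifnot(locus %in% names(locus_defs), !missing(seed))
  def <- locus_defs[[locus]]
  enum <- allele_enumerations()[[locus]]
  bad <- setdiff(names(type_counts), enum)
  if (length(bad)) {
    stop("allele type(s) not in the ", locus, " enumeration: ",
         paste(bad, collapse = ", "))
  }
  type_counts <- type_counts[type_counts > 0]
  n <- sum(type_counts)
  if (n == 0L) stop("no sequences requested")

  with_seed(seed, {
    L <- def$length
    base <- sample(acgt, L, replace = TRUE)
    for (d in def$diagnostics) {
      if (d$kind == "SNP") base[d$position] <- d$ref_state
    }
    reserved <- reserved_columns(def)
    free <- setdiff(seq_len(L), reserved)
    if (target_S + 3L * n_indels > length(free)) {
      stop("target S and indel events exceed available non-diagnostic columns")
    }

    truth_types <- rep(names(type_counts), times = type_counts)
    ids <- sprintf("%s_%03d", locus, seq_len(n))
    # whole-amplicon absence: only the SaF gene is removed entirely
    is_absent <- truth_types == "SaFX"
    # every X-type allele rides on the SaFX deletion (assay-positive)
    is_carrier <- truth_types %in% c("SaFX", "SaM+X", "SaM-X")

    rows <- list()
    for (i in seq_len(n)) {
      if (is_absent[i]) next
      s <- base
      tp <- truth_types[i]
      tag <- names(def$type_map)[match(sub("X$", "", tp), def$type_map)]
      if (identical(tp, "s5-n")) tag <- "i"  # wc deletion on indica background
      for (d in def$diagnostics) {
        if (d$kind == "SNP") {
          if (!is.na(tag)) s[d$position] <- state_for_tag(d, tag)
        } else {
          # insertion-presence diagnostic (DPL1): 'present' carries
          # sequence, 'absent' shows a gap block
          block <- d$position:(d$position + d$indel_length - 1L)
          present <- identical(unname(def$type_map[d$state_labels[["present"]]]), tp)
          if (!present) s[block] <- "-"
        }
      }
      for (dd in def$deletion_defs) {
        if (identical(dd$detection_mode, "sequence-gap") &&
            identical(unname(lookup(def$deletion_types, dd$name, "")), tp)) {
          s[dd$start:(dd$end - 1L)] <- "-"
        }
      }
      rows[[ids[i]]] <- s
    }

    aln <- if (length(rows)) do.call(rbind, rows) else NULL

    if (!is.null(aln) && nrow(aln) > 1L) {
      # Neutral variation is applied to haplotype classes, so the
      # distinct-haplotype count is controlled exactly: without a
      # haplotype target every sequence is its own class (free
      # variation); with a target, sequences are partitioned into
      # n_haplotypes classes nested within allele types and each class
      # receives a distinct presence/absence profile over the
      # segregating sites.
      row_type <- truth_types[!is_absent][match(rownames(aln),
                                                ids[!is_absent])]
      if (is.null(n_haplotypes)) {
        class_of <- seq_len(nrow(aln))
      } else {
        types_present <- unique(row_type)
        if (n_haplotypes < length(types_present)) {
          stop("cannot collapse ", length(types_present),
               " allele types into ", n_haplotypes, " haplotypes")
        }
        if (n_haplotypes > nrow(aln)) {
          stop("haplotype target exceeds the number of sequences")
        }
        # distribute classes over types proportionally, >= 1 each
        sizes <- table(row_type)[types_present]
        k_per <- pmax(1L, round(n_haplotypes * as.vector(sizes) / sum(sizes)))
        while (sum(k_per) != n_haplotypes) {
          i <- if (sum(k_per) > n_haplotypes) {
            which(k_per == max(k_per))[1]
          } else {
            which(as.vector(sizes) - k_per == max(as.vector(sizes) - k_per))[1]
          }
          k_per[i] <- k_per[i] + sign(n_haplotypes - sum(k_per))
        }
        if (any(k_per > as.vector(sizes))) {
          stop("haplotype target exceeds sequences available in a type")
        }
        class_of <- integer(nrow(aln))
        offset <- 0L
        for (ti in seq_along(types_present)) {
          idx <- which(row_type == types_present[ti])
          class_of[idx] <- offset +
            (seq_along(idx) - 1L) %% k_per[ti] + 1L
          offset <- offset + k_per[ti]
        }
      }
      K <- max(class_of)

      # diagnostic SNP columns that already segregate in this mix count
      # toward the target (survey S totals include them)
      diag_seg <- 0L
      for (d in def$diagnostics) {
        if (d$kind == "SNP" &&
            length(unique(aln[, d$position])) >= 2L) {
          diag_seg <- diag_seg + 1L
        }
      }
      neutral_S <- max(0L, target_S - diag_seg)
      site_cols <- if (neutral_S > 0L) sample(free, neutral_S) else integer()
      if (length(site_cols)) {
        if (is.null(n_haplotypes)) {
          prof <- matrix(0L, K, length(site_cols))
          for (j in seq_along(site_cols)) {
            prof[sample.int(K, sample.int(K - 1L, 1L)), j] <- 1L
          }
        } else {
          # distinct class profiles over the segregating sites
          if (K > 2^length(site_cols)) {
            stop("target S too small to realise ", K,
                 " distinct haplotypes")
          }
          repeat {
            prof <- matrix(stats::rbinom(K * length(site_cols), 1L, 0.5),
                           K)
            keys <- apply(prof, 1, paste0, collapse = "")
            constant <- any(colSums(prof) %in% c(0L, K))
            if (anyDuplicated(keys) == 0L && !constant) break
          }
        }
        for (j in seq_along(site_cols)) {
          cc <- site_cols[j]
          alt <- sample(setdiff(acgt, base[cc]), 1L)
          who <- which(prof[class_of, j] == 1L)
          aln[who, cc] <- alt
        }
      }

      free2 <- setdiff(free, site_cols)
      # extra shared indel events: 3-bp gap runs with identical spans,
      # applied per haplotype class so they never split a class
      if (n_indels > 0L) {
        cand <- free2[(free2 + 1L) %in% free2 & (free2 + 2L) %in% free2]
        keep <- integer(); last_end <- -2L
        for (st in cand) {
          if (st > last_end + 1L) { keep <- c(keep, st); last_end <- st + 2L }
        }
        if (length(keep) < n_indels) stop("not enough free columns for indels")
        for (st in sample(keep, n_indels)) {
          classes <- sample.int(K, sample.int(max(K - 1L, 1L), 1L))
          who <- which(class_of %in% classes)
          aln[who, st:(st + 2L)] <- "-"
        }
      }
      if (!is.null(n_haplotypes)) {
        got <- nrow(enumerate_haplotypes(aln))
        if (got != n_haplotypes) {
          stop("internal error: realised ", got, " haplotypes, expected ",
               n_haplotypes)
        }
      }
    }

    # whole-locus amplification failures
    miss <- rep(FALSE, n)
    if (missing_rate > 0) {
      miss <- stats::runif(n) < missing_rate & !is_absent
      if (!is.null(aln)) {
        aln <- aln[!rownames(aln) %in% ids[miss], , drop = FALSE]
      }
    }

    amp <- NULL
    if (locus %in% c("SaF", "SaM")) {
      amp <- do.call(rbind, lapply(seq_len(n), function(i) {
        if (is_carrier[i]) {
          data.frame(accession = ids[i], locus = locus,
                     primer_set = c("SaF", "SaFdel"),
                     outcome = c("fail", "success"),
                     stringsAsFactors = FALSE)
        } else {
          data.frame(accession = ids[i], locus = locus,
                     primer_set = "SaF",
                     outcome = if (miss[i]) "fail" else "success",
                     stringsAsFactors = FALSE)
        }
      }))
    }

    list(alignment = aln,
         truth = data.frame(seq_id = ids, allele_type = truth_types,
                            missing = miss, stringsAsFactors = FALSE),
         amp_calls = amp,
         safx_carriers = ids[is_carrier])
  })
}

#' Generate a genotype panel from marginal counts
#'
#' Builds accession-level records whose per-population, per-locus
#' allele counts equal the supplied table exactly, so
#' [allele_type_frequencies()] on the output reproduces the input
#' percentages under the module's rounding rule. Wild-group alleles are
#' paired into diploid accessions; all other groups are haploid.
#'
#' @param counts data.frame with columns `group`, `locus`, `allele`,
#'   `count`
#' @param seed integer seed (allele-to-accession assignment is
#'   shuffled deterministically)
#' @return list with `metadata`, `calls` and the assembled `panel`
#' @export
generate_panel_from_marginals <- function(counts, seed = 1L) {
  stopifnot(all(c("group", "locus", "allele", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("negative count")
  enums <- allele_enumerations()
  for (i in seq_len(nrow(counts))) {
    if (!counts$locus[i] %in% names(enums)) {
      stop("unknown locus '", counts$locus[i], "'")
    }
    if (!counts$allele[i] %in% enums[[counts$locus[i]]]) {
      stop("allele '", counts$allele[i], "' not in the ",
           counts$locus[i], " enumeration")
    }
  }
  with_seed(seed, {
    calls <- list()
    meta <- list()
    for (g in unique(counts$group)) {
      sub <- counts[counts$group == g, ]
      diploid <- g == "wild"
      per_acc <- if (diploid) 2L else 1L
      n_acc <- 0L
      for (loc in unique(sub$locus)) {
        al <- rep(sub$allele[sub$locus == loc], sub$count[sub$locus == loc])
        if (!length(al)) next
        al <- sample(al)
        acc_idx <- ceiling(seq_along(al) / per_acc)
        n_acc <- max(n_acc, max(acc_idx))
        calls[[paste(g, loc)]] <- data.frame(
          accession = sprintf("%s_%02d", g, acc_idx),
          locus = loc, allele = al, stringsAsFactors = FALSE)
      }
      if (n_acc > 0L) {
        meta[[g]] <- data.frame(accession = sprintf("%s_%02d", g, seq_len(n_acc)),
                                group = g, diploid = diploid,
                                stringsAsFactors = FALSE)
      }
    }
    empty_calls <- data.frame(accession = character(), locus = character(),
                              allele = character(), stringsAsFactors = FALSE)
    empty_meta <- data.frame(accession = character(), group = character(),
                             diploid = logical(), stringsAsFactors = FALSE)
    calls <- if (length(calls)) do.call(rbind, unname(calls)) else empty_calls
    meta <- if (length(meta)) do.call(rbind, unname(meta)) else empty_meta
    rownames(calls) <- rownames(meta) <- NULL
    list(metadata = meta, calls = calls,
         panel = build_panel(meta, calls))
  })
}

#' Generate noisy triplicate pollen measurements
#'
#' Each individual's true mean percent non-viable pollen comes from its
#' genotype's effect; three fields of view are drawn around it with
#' Gaussian noise, clamped to [0, 100], and converted to
#' viable/non-viable grain counts.
#'
#' @param effects named numeric vector: genotype label -> true mean
#'   percent non-viable (values in [0, 100])
#' @param noise_sd field-to-field standard deviation (percent points)
#' @param n_per_genotype individuals per genotype (named vector or
#'   single number)
#' @param seed integer seed
#' @param grains_per_field total grains scored per field of view
#' @return data.frame with `accession`, `genotype`, `field`, `viable`,
#'   `nonviable`, `true_mean`
#' @export
generate_pollen_dataset <- function(effects, noise_sd, n_per_genotype,
                                    seed, grains_per_field = 200L) {
  stopifnot(all(effects >= 0), all(effects <= 100), noise_sd >= 0)
  if (length(n_per_genotype) == 1L && is.null(names(n_per_genotype))) {
    n_per_genotype <- setNames(rep(n_per_genotype, length(effects)),
                               names(effects))
  }
  with_seed(seed, {
    out <- list()
    for (g in names(effects)) {
      n <- lookup(n_per_genotype, g, 0L)
      if (n == 0L) next
      for (i in seq_len(n)) {
        acc <- sprintf("%s_ind%02d", gsub("[^A-Za-z0-9+-]", "", g), i)
        p <- pmin(100, pmax(0, effects[[g]] + stats::rnorm(3, 0, noise_sd)))
        nv <- round(grains_per_field * p / 100)
        out[[paste(g, i)]] <- data.frame(
          accession = acc, genotype = g, field = 1:3,
          viable = grains_per_field - nv, nonviable = nv,
          true_mean = effects[[g]], stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, unname(out))
    rownames(out) <- NULL
    out
  })
}

#' Generate a two-clade test alignment
#'
#' Two clearly separated clades: clade members differ from their clade
#' consensus at a few sites, the two consensus sequences differ at many
#' sites. Used to exercise bootstrap support for a deep split.
#'
#' @param n_a,n_b sequences per clade
#' @param L alignment length
#' @param d_between substitutions separating the clade consensuses
#' @param d_within private substitutions per sequence
#' @param seed integer seed
#' @return character alignment matrix; rownames `A*`/`B*`
#' @export
generate_clade_alignment <- function(n_a = 4L, n_b = 4L, L = 600L,
                                     d_between = 60L, d_within = 2L,
                                     seed = 1L) {
  with_seed(seed, {
    consA <- sample(acgt, L, replace = TRUE)
    consB <- consA
    flip <- sample.int(L, d_between)
    consB[flip] <- vapply(consB[flip],
                          function(x) sample(setdiff(acgt, x), 1L), "")
    mk <- function(cons, k) {
      s <- cons
      pos <- sample(setdiff(seq_len(L), flip), k)
      s[pos] <- vapply(s[pos], function(x) sample(setdiff(acgt, x), 1L), "")
      s
    }
    rows <- c(lapply(seq_len(n_a), function(i) mk(consA, d_within)),
              lapply(seq_len(n_b), function(i) mk(consB, d_within)))
    aln <- do.call(rbind, rows)
    rownames(aln) <- c(sprintf("A%d", seq_len(n_a)),
                       sprintf("B%d", seq_len(n_b)))
    aln
  })
}
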