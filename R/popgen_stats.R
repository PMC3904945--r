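#' @title Diversity statistics for locus alignments
#'
#' @description
#' Per-population, per-locus summary statistics of nucleotide variation:
#' segregating sites (S), average pairwise nucleotide diversity (pi,
#' Nei & Li), Watterson's estimator (theta_W) and Tajima's D, plus
#' haplotype and indel-event counts. Gap handling follows the common
#' sequence-analysis convention: alignment columns containing any gap
#' are excluded from S, from theta_W's site denominator and from the
#' complete-deletion pairwise counts that enter Tajima's D; pi by
#' default uses pairwise deletion (each pair compared over its own
#' gap-free sites), switchable to complete deletion.
#'
#' @name popgen_stats
NULL

acgt <- c("A", "C", "G", "T")

# columns with no gap in any sequence
gap_free_columns <- function(aln) {
  which(colSums(aln == "-") == 0L)
}

#' Count segregating sites
#'
#' A column is segregating when it carries at least two distinct states
#' among A/C/G/T. Columns containing any gap are excluded (and likewise
#' from the per-site denominators of the estimators); `N`s are ignored
#' as missing but do not disqualify a column.
#'
#' @param aln alignment (see [as_alignment()]), at least 2 sequences
#' @return integer S
#' @export
segregating_sites <- function(aln) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  cols <- gap_free_columns(aln)
  if (length(cols) == 0L) return(0L)
  sum(vapply(cols, function(j) {
    length(unique(aln[aln[, j] %in% acgt, j])) >= 2L
  }, logical(1)))
}

# number of differing sites and comparable sites for one sequence pair
pair_diff <- function(a, b) {
  ok <- a %in% acgt & b %in% acgt
  c(diff = sum(a[ok] != b[ok]), sites = sum(ok))
}

#' Average pairwise nucleotide diversity (pi)
#'
#' Mean over all n(n-1)/2 sequence pairs of the per-site difference
#' proportion. Under pairwise deletion (default) each pair is compared
#' over its own gap-free A/C/G/T sites; under complete deletion only
#' columns gap-free across the whole alignment are used.
#'
#' @param aln alignment, n >= 2
#' @param deletion `"pairwise"` or `"complete"`
#' @return per-site pi; `NaN` (flagged undefined) when no pair has
#'   comparable sites
#' @export
nucleotide_diversity <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  if (deletion == "complete") aln <- aln[, gap_free_columns(aln), drop = FALSE]
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pair_diff(aln[i, ], aln[j, ])
      if (d[["sites"]] > 0L) vals <- c(vals, d[["diff"]] / d[["sites"]])
    }
  }
  if (length(vals) == 0L) return(NaN)
  # pairs with zero comparable sites are dropped from the mean
  sum(vals) / (n * (n - 1) / 2)
}

#' Watterson's estimator of nucleotide variation (theta_W)
#'
#' theta_W = S / (a1 * L), a1 = sum_{i=1}^{n-1} 1/i, with L the number
#' of gap-free columns.
#'
#' @param aln alignment, n >= 2
#' @return per-site theta_W (0 when S = 0; `NaN` when no gap-free sites)
#' @export
watterson_theta <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  L <- length(gap_free_columns(aln))
  if (L == 0L) return(NaN)
  S <- segregating_sites(aln)
  a1 <- sum(1 / seq_len(n - 1L))
  S / (a1 * L)
}

# mean pairwise difference count over gap-free columns (complete
# deletion; the quantity entering Tajima's D)
mean_pairwise_differences <- function(aln) {
  aln <- aln[, gap_free_columns(aln), drop = FALSE]
  n <- nrow(aln)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + pair_diff(aln[i, ], aln[j, ])[["diff"]]
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1)) with k the mean pairwise
#' difference count and the standard constants: a1 = sum 1/i,
#' a2 = sum 1/i^2 (i = 1..n-1), b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#' Undefined (returns `NA`) when fewer than four sequences are
#' available or when there is no segregating site; tables render this
#' as "n/a".
#'
#' @param aln alignment
#' @return D, or `NA_real_` when undefined
#' @export
tajimas_d <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 4L) return(NA_real_)
  S <- segregating_sites(aln)
  if (S < 1L) return(NA_real_)
  k <- mean_pairwise_differences(aln)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Count indel events in an alignment
#'
#' Contiguous gap runs with identical start and end shared across
#' sequences count as one indel event (one event per distinct run
#' span), so a 136-bp deletion shared by five sequences is a single
#' event.
#'
#' @param aln alignment
#' @return integer number of distinct indel events
#' @export
count_indels <- function(aln) {
  aln <- as_alignment(aln)
  runs <- character()
  for (i in seq_len(nrow(aln))) {
    r <- rle(aln[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap <- which(r$values)
    if (length(gap)) {
      runs <- c(runs, paste0(starts[gap], "-", ends[gap]))
    }
  }
  length(unique(runs))
}

#' Per-group, per-locus diversity summary
#'
#' @param aln alignment for one locus restricted to one population
#' @param group,locus labels carried into the output
#' @return one-row data.frame with n, S, pi, theta_w, tajima_d,
#'   n_haplotypes, n_indels
#' @export
diversity_stats <- function(aln, group = NA_character_,
                            locus = NA_character_) {
  aln <- as_alignment(aln)
  data.frame(group = group, locus = locus, n = nrow(aln),
             S = segregating_sites(aln),
             pi = nucleotide_diversity(aln),
             theta_w = watterson_theta(aln),
             tajima_d = tajimas_d(aln),
             n_haplotypes = nrow(enumerate_haplotypes(aln)),
             n_indels = count_indels(aln),
             stringsAsFactors = FALSE)
}

#' Phase heterozygotes by haplotype subtraction
#'
#' Clark's parsimony phasing: homozygous individuals seed the known
#' haplotype set; each heterozygote compatible with a known haplotype
#' is resolved by subtracting it (the complement takes the other allele
#' at every heterozygous site), and newly inferred haplotypes join the
#' known set; iteration continues while new haplotypes appear.
#' Heterozygotes are processed in input order (the algorithm's
#' well-known order dependence); unresolved records are flagged, never
#' guessed.
#'
#' @param genotypes named list; each element a character vector of
#'   site genotypes, `"A"` for a homozygous site or the two alleles
#'   sorted and pasted (`"AG"`) for a heterozygous site
#' @param known_haplotypes optional character matrix of already-known
#'   haplotypes (rows)
#' @return list with `phased` (list of per-accession lists:
#'   `haplotype_a`, `haplotype_b`, `resolved_by`), `unresolved`
#'   (character vector of accession names) and `known` (matrix of all
#'   known haplotypes at exit)
#' @export
clark_phase <- function(genotypes, known_haplotypes = NULL) {
  stopifnot(is.list(genotypes), length(genotypes) > 0L)
  L <- unique(lengths(genotypes))
  if (length(L) != 1L) stop("genotypes differ in length")

  is_het <- function(g) nchar(g) > 1L
  known <- list()
  add_known <- function(h) {
    key <- paste0(h, collapse = "")
    if (!key %in% names(known)) known[[key]] <<- h
  }
  if (!is.null(known_haplotypes)) {
    for (i in seq_len(nrow(known_haplotypes))) add_known(known_haplotypes[i, ])
  }

  phased <- list()
  hets <- character()
  for (nm in names(genotypes)) {
    g <- genotypes[[nm]]
    if (!any(is_het(g))) {
      phased[[nm]] <- list(haplotype_a = g, haplotype_b = g,
                           resolved_by = "homozygote")
      add_known(g)
    } else {
      hets <- c(hets, nm)
    }
  }

  if (length(hets) && length(known) == 0L) {
    return(list(phased = phased, unresolved = hets,
                known = do.call(rbind, unname(known)),
                note = "no homozygote seed available"))
  }

  repeat {
    progressed <- FALSE
    for (nm in hets) {
      g <- genotypes[[nm]]
      for (key in names(known)) {
        h <- known[[key]]
        compatible <- all(mapply(function(gi, hi) {
          hi %in% strsplit(gi, "")[[1]]
        }, g, h))
        if (compatible) {
          comp <- mapply(function(gi, hi) {
            al <- strsplit(gi, "")[[1]]
            if (length(al) == 1L) al else setdiff(al, hi)[1]
          }, g, h)
          phased[[nm]] <- list(haplotype_a = unname(h),
                               haplotype_b = unname(comp),
                               resolved_by = key)
          add_known(unname(comp))
          hets <- setdiff(hets, nm)
          progressed <- TRUE
          break
        }
      }
      if (progressed) break
    }
    if (!progressed) break
  }
  list(phased = phased, unresolved = hets,
       known = do.call(rbind, unname(known)))
}
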