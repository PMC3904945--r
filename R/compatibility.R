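#' @title Bateson-Dobzhansky-Muller sterility rules of the three systems
#'
#' @description
#' The three cloned hybrid sterility systems act in the F1:
#' \itemize{
#'   \item \strong{Sa} (pollen): an F1 heterozygous for functional
#'     \code{SaM+}/\code{SaM-} alleles in the presence of at least one
#'     functional \code{SaF+} selectively aborts the SaM- bearing
#'     microspores — male semi-sterility, usually about 50%. Any
#'     X-suffixed allele (\code{SaFX}, \code{SaM+X}, \code{SaM-X})
#'     derives from the 8.6-kb deletion and produces no functional
#'     product, so X carriers escape the interaction (the
#'     wide-compatibility behaviour supported by the crossing data);
#'     an `"unknown"` mode abstains instead.
#'   \item \strong{s5} (embryo sac): the \code{s5-i}/\code{s5-j}
#'     heterodimer causes embryo-sac abortion, reported to reduce
#'     spikelet fertility by 46%; any \code{s5-n} (136-bp deletion,
#'     non-functional) allele confers wide compatibility.
#'   \item \strong{DPL} (pollen): pollen carrying non-functional
#'     alleles at both duplicate loci (\code{DPL1-K-} and
#'     \code{DPL2-N-}) is non-viable; the loci assort independently
#'     (chromosomes 1 and 6), so the viable-gamete fraction follows
#'     from enumerating the four gamete classes.
#' }
#' Systems are combined multiplicatively into one relative-fertility
#' scalar — a modeling assumption (the systems are evaluated separately
#' in the source analyses and act through different mechanisms), kept
#' explicit in the per-system outputs.
#'
#' @name compatibility_model
NULL

# null (no functional product) alleles per gene
is_functional <- function(allele) {
  !allele %in% c("SaFX", "SaM+X", "SaM-X", "s5-n")
}

diploid <- function(g) {
  if (length(g) == 1L) rep(g, 2L) else g
}

#' Sa-system verdict for an F1 genotype
#'
#' @param sam character vector of 1 (homozygous) or 2 SaM alleles
#' @param saf character vector of 1 or 2 SaF alleles
#' @param effect_size expected pollen loss in incompatible F1s
#'   (default 0.5, the "usually about 50%" semi-sterility)
#' @param x_mode `"null"` treats X alleles as complete nulls;
#'   `"unknown"` abstains (returns `NA` verdict) for X-carrying F1s
#' @return list with `verdict` (`"compatible"`/`"semi-sterile"`/`NA`),
#'   `viable_fraction` and `rationale`
#' @export
evaluate_sa <- function(sam, saf, effect_size = 0.5,
                        x_mode = c("null", "unknown")) {
  x_mode <- match.arg(x_mode)
  sam <- diploid(sam); saf <- diploid(saf)
  enums <- allele_enumerations()
  if (!all(sam %in% enums$SaM)) stop("unknown SaM allele label")
  if (!all(saf %in% enums$SaF)) stop("unknown SaF allele label")
  has_x <- any(!is_functional(c(sam, saf)))
  if (x_mode == "unknown" && has_x) {
    return(list(verdict = NA_character_, viable_fraction = NA_real_,
                rationale = "X allele present; abstaining in unknown mode"))
  }
  func_sam <- sam[is_functional(sam)]
  het <- all(c("SaM+", "SaM-") %in% func_sam) && length(func_sam) == 2L
  saf_plus <- any(saf == "SaF+")
  if (het && saf_plus) {
    list(verdict = "semi-sterile", viable_fraction = 1 - effect_size,
         rationale = "functional SaM heterozygote with a functional SaF+: selective abortion of SaM- microspores")
  } else {
    list(verdict = "compatible", viable_fraction = 1,
         rationale = if (has_x) "X allele(s) supply no functional product; interaction not triggered"
                     else "no functional SaM heterozygote with SaF+")
  }
}

#' s5-system verdict for an F1 genotype
#'
#' @param s5 character vector of 1 or 2 s5 alleles
#' @param effect_size spikelet-fertility reduction in the
#'   incompatible s5-i/s5-j F1 (default 0.46)
#' @return list with `verdict`, `fertility_reduction`,
#'   `viable_fraction` (1 - reduction) and `rationale`
#' @export
evaluate_s5 <- function(s5, effect_size = 0.46) {
  s5 <- diploid(s5)
  if (!all(s5 %in% allele_enumerations()$s5)) stop("unknown s5 allele label")
  if (setequal(s5, c("s5-i", "s5-j")) && length(unique(s5)) == 2L) {
    list(verdict = "semi-sterile", fertility_reduction = effect_size,
         viable_fraction = 1 - effect_size,
         rationale = "s5-i/s5-j heterodimer causes embryo-sac abortion")
  } else {
    list(verdict = "compatible", fertility_reduction = 0,
         viable_fraction = 1,
         rationale = if (any(s5 == "s5-n")) "s5-n is non-functional: wide compatibility"
                     else "no i/j heterodimer")
  }
}

#' DPL-system verdict for an F1 genotype
#'
#' Enumerates the four gamete classes under independent assortment;
#' gametes carrying both non-functional alleles (`DPL1-K-` and
#' `DPL2-N-`) are non-viable.
#'
#' @param dpl1 character vector of 1 or 2 DPL1 alleles
#' @param dpl2 character vector of 1 or 2 DPL2 alleles
#' @return list with `verdict`, `viable_fraction` and `rationale`
#' @export
evaluate_dpl <- function(dpl1, dpl2) {
  dpl1 <- diploid(dpl1); dpl2 <- diploid(dpl2)
  enums <- allele_enumerations()
  if (!all(dpl1 %in% enums$DPL1)) stop("unknown DPL1 allele label")
  if (!all(dpl2 %in% enums$DPL2)) stop("unknown DPL2 allele label")
  p_k <- mean(dpl1 == "DPL1-K-")
  p_n <- mean(dpl2 == "DPL2-N-")
  dead <- p_k * p_n
  list(verdict = if (dead > 0) "semi-sterile" else "compatible",
       viable_fraction = 1 - dead,
       rationale = sprintf(
         "fraction %.2f of gametes carry DPL1-K- with DPL2-N- and are non-viable",
         dead))
}

#' Parse a haploid slash-notation genotype string
#'
#' Accepts the field's compact notation, e.g.
#' `"SaM+X/SaFX;s5-n;DPL1-N+;DPL2-K+"`: loci separated by `;` or `/`
#' between different genes, `//` separating the two halves of an
#' explicit diploid genotype per gene pair. Each allele token is
#' assigned to its locus by name.
#'
#' @param s genotype string
#' @return named list locus -> character vector of 1 or 2 alleles
#' @export
parse_genotype <- function(s) {
  enums <- allele_enumerations()
  tokens <- unlist(strsplit(s, "[;/]+"))
  tokens <- trimws(tokens[nzchar(trimws(tokens))])
  out <- list()
  for (tk in tokens) {
    loc <- NULL
    for (nm in names(enums)) if (tk %in% enums[[nm]]) loc <- nm
    if (is.null(loc)) stop("unrecognised allele token '", tk, "'")
    out[[loc]] <- c(out[[loc]], tk)
  }
  for (nm in names(out)) {
    if (length(out[[nm]]) > 2L) {
      stop("more than two alleles given for ", nm)
    }
  }
  out
}

# F1 genotype classes at one locus with their probabilities: each
# parent transmits either allele with probability 1/2
f1_locus_combos <- function(a, b) {
  a <- as.list(diploid(a)); b <- as.list(diploid(b))
  combos <- list()
  for (x in a) for (y in b) combos <- c(combos, list(sort(c(x, y))))
  keys <- vapply(combos, paste, "", collapse = "/")
  uniq <- !duplicated(keys)
  list(genotypes = combos[uniq],
       prob = as.vector(table(keys)[keys[uniq]]) / length(keys))
}

#' F1 genotype(s) of a cross
#'
#' The F1 takes one allele from each parent per locus; inbred
#' (haploid-notation) parents are treated as homozygous, so their cross
#' yields a single F1 genotype. Heterozygous (diploid) parents yield
#' the set of equally likely F1 genotypes, all returned. A locus
#' missing from either parent is marked unpredictable; other loci are
#' still evaluated. Symmetric in the parents.
#'
#' @param parent_a,parent_b named lists locus -> allele vector (1 or
#'   2), or genotype strings (see [parse_genotype()])
#' @return list with `combos` (per locus: list of possible F1 diploid
#'   genotypes, equally likely) and `unpredictable` (loci typed in only
#'   one parent or neither)
#' @export
f1_genotype <- function(parent_a, parent_b) {
  if (is.character(parent_a)) parent_a <- parse_genotype(parent_a)
  if (is.character(parent_b)) parent_b <- parse_genotype(parent_b)
  loci <- union(names(parent_a), names(parent_b))
  shared <- intersect(names(parent_a), names(parent_b))
  combos <- lapply(shared, function(loc) {
    f1_locus_combos(parent_a[[loc]], parent_b[[loc]])
  })
  names(combos) <- shared
  list(combos = lapply(combos, `[[`, "genotypes"),
       probs = lapply(combos, `[[`, "prob"),
       unpredictable = setdiff(loci, shared))
}

# evaluate one fully specified F1 genotype (named list of length-2
# allele vectors); returns per-system viable fractions (NA = system
# not typed)
evaluate_f1_systems <- function(f1, sa_effect = 0.5, s5_effect = 0.46,
                                x_mode = "null") {
  sa <- if (all(c("SaM", "SaF") %in% names(f1))) {
    evaluate_sa(f1$SaM, f1$SaF, effect_size = sa_effect, x_mode = x_mode)
  }
  s5 <- if ("s5" %in% names(f1)) evaluate_s5(f1$s5, effect_size = s5_effect)
  dpl <- if (all(c("DPL1", "DPL2") %in% names(f1))) {
    evaluate_dpl(f1$DPL1, f1$DPL2)
  }
  list(Sa = sa, s5 = s5, DPL = dpl)
}

#' Predict the compatibility of a cross
#'
#' Forms the F1 genotype(s) and runs all three system rules. Per
#' system, the expected viable fraction is averaged over the equally
#' likely F1 genotypes (a single genotype for homozygous parents); the
#' combined predicted relative fertility is the product of the
#' per-system fractions over the systems typed in both parents.
#' Symmetric in the parents; self-crosses of homozygous parents are
#' always fully compatible.
#'
#' @param parent_a,parent_b genotypes (named lists or strings)
#' @param sa_effect,s5_effect effect sizes (defaults 0.5 and 0.46)
#' @param x_mode see [evaluate_sa()]
#' @return object of class `cross_prediction`: per-system verdicts and
#'   expected viable fractions, `combined_fertility`, `systems_used`,
#'   `unpredictable` loci, and rationale strings
#' @export
predict_cross <- function(parent_a, parent_b, sa_effect = 0.5,
                          s5_effect = 0.46, x_mode = "null") {
  f1 <- f1_genotype(parent_a, parent_b)
  combos <- f1$combos
  probs <- f1$probs

  expand <- function(loci) {
    # cartesian product of per-locus F1 classes, with joint weights
    grids <- combos[loci]
    wts <- probs[loci]
    idx <- expand.grid(lapply(grids, seq_along))
    lapply(seq_len(nrow(idx)), function(r) {
      g <- lapply(seq_along(loci), function(k) grids[[k]][[idx[r, k]]])
      names(g) <- loci
      w <- prod(vapply(seq_along(loci),
                       function(k) wts[[k]][idx[r, k]], 1))
      list(genotype = g, weight = w)
    })
  }

  systems <- list(
    Sa = c("SaM", "SaF"),
    s5 = "s5",
    DPL = c("DPL1", "DPL2")
  )
  out <- list()
  for (sys_nm in names(systems)) {
    need <- systems[[sys_nm]]
    if (!all(need %in% names(combos))) {
      out[[sys_nm]] <- list(verdict = NA_character_,
                            viable_fraction = NA_real_,
                            rationale = "locus not typed in both parents")
      next
    }
    f1s <- expand(need)
    evals <- lapply(f1s, function(e) {
      g <- e$genotype
      switch(sys_nm,
             Sa = evaluate_sa(g$SaM, g$SaF, effect_size = sa_effect,
                              x_mode = x_mode),
             s5 = evaluate_s5(g$s5, effect_size = s5_effect),
             DPL = evaluate_dpl(g$DPL1, g$DPL2))
    })
    fr <- vapply(evals, `[[`, numeric(1), "viable_fraction")
    wts <- vapply(f1s, `[[`, numeric(1), "weight")
    verdicts <- vapply(evals, `[[`, character(1), "verdict")
    out[[sys_nm]] <- list(
      verdict = if (all(is.na(verdicts))) NA_character_
                else if (any(verdicts == "semi-sterile", na.rm = TRUE)) "semi-sterile"
                else "compatible",
      viable_fraction = sum(wts * fr) / sum(wts),
      rationale = evals[[1]]$rationale)
  }
  used <- names(out)[!vapply(out, function(x) is.na(x$viable_fraction),
                             logical(1))]
  combined <- prod(vapply(out[used], `[[`, numeric(1), "viable_fraction"))
  structure(list(systems = out, systems_used = used,
                 combined_fertility = if (length(used)) combined else NA_real_,
                 unpredictable = f1$unpredictable),
            class = "cross_prediction")
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat("Cross prediction\n")
  for (nm in names(x$systems)) {
    s <- x$systems[[nm]]
    cat(sprintf("  %-4s %-12s viable fraction %s\n", nm,
                ifelse(is.na(s$verdict), "(untyped)", s$verdict),
                format(s$viable_fraction, digits = 3)))
  }
  cat(sprintf("  combined relative fertility: %s\n",
              format(x$combined_fertility, digits = 3)))
  invisible(x)
}

# panel rows -> per-accession genotype list
panel_genotypes <- function(panel) {
  out <- list()
  for (acc in unique(panel$accession)) {
    rows <- panel[panel$accession == acc, ]
    g <- list()
    for (loc in unique(rows$locus)) {
      al <- rows$allele[rows$locus == loc]
      al <- al[!is.na(al)]
      if (length(al)) g[[loc]] <- al
    }
    out[[acc]] <- list(group = rows$group[1], genotype = g)
  }
  out
}

#' Expected compatibility between populations
#'
#' For each ordered pair of populations, the mean combined predicted
#' relative fertility over all individual-by-individual crosses.
#' Crosses missing a system in either parent skip that system (count
#' reported in the `n_partial` attribute); pairs of empty groups are
#' `NA`.
#'
#' @param panel an `hi_panel`
#' @param groups populations to include (default: those present)
#' @inheritParams predict_cross
#' @return square numeric matrix of mean fertilities with attribute
#'   `n_crosses` and `n_partial` matrices
#' @export
population_barrier_matrix <- function(panel, groups = NULL,
                                      sa_effect = 0.5, s5_effect = 0.46,
                                      x_mode = "null") {
  gts <- panel_genotypes(panel)
  grp_of <- vapply(gts, `[[`, character(1), "group")
  if (is.null(groups)) {
    groups <- intersect(table1_group_order(), unique(grp_of))
  }
  M <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  n_crosses <- n_partial <- matrix(0L, length(groups), length(groups),
                                   dimnames = dimnames(M))
  # cache: fertility of a cross depends only on the genotype pair
  cache <- new.env(parent = emptyenv())
  fert <- function(ga, gb) {
    key <- paste(c(deparse(ga), "#", deparse(gb)), collapse = ";")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- predict_cross(ga, gb, sa_effect = sa_effect,
                       s5_effect = s5_effect, x_mode = x_mode)
    v <- list(f = p$combined_fertility,
              partial = length(p$systems_used) < 3L)
    cache[[key]] <- v
    v
  }
  for (ga_nm in groups) {
    for (gb_nm in groups) {
      ia <- names(gts)[grp_of == ga_nm]
      ib <- names(gts)[grp_of == gb_nm]
      if (!length(ia) || !length(ib)) next
      vals <- numeric(); partial <- 0L
      for (a in ia) for (b in ib) {
        v <- fert(gts[[a]]$genotype, gts[[b]]$genotype)
        if (!is.na(v$f)) vals <- c(vals, v$f)
        if (v$partial) partial <- partial + 1L
      }
      if (length(vals)) M[ga_nm, gb_nm] <- mean(vals)
      n_crosses[ga_nm, gb_nm] <- length(vals)
      n_partial[ga_nm, gb_nm] <- partial
    }
  }
  attr(M, "n_crosses") <- n_crosses
  attr(M, "n_partial") <- n_partial
  M
}
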