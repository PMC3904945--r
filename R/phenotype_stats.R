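#' Mean percent non-viable pollen for one individual
#'
#' Pollen quality is scored as a non-viable-to-total ratio in each of
#' three fixed-area fields of view (starch-staining assay: viable
#' grains stain dark, non-viable stay clear); the per-individual value
#' is the mean over fields of 100 * nonviable / (viable + nonviable).
#'
#' @param fields a 3-row matrix or data.frame with columns `viable` and
#'   `nonviable` (counts per field of view)
#' @return mean percent non-viable, in [0, 100]
#' @export
nonviable_percent <- function(fields) {
  fields <- as.data.frame(fields)
  stopifnot(all(c("viable", "nonviable") %in% names(fields)))
  if (nrow(fields) != 3L) {
    stop("expected exactly 3 fields of view, got ", nrow(fields))
  }
  tot <- fields$viable + fields$nonviable
  if (any(tot <= 0)) {
    stop("empty field of view at row ", which(tot <= 0)[1])
  }
  mean(100 * fields$nonviable / tot)
}

#' Pollen grain concentration for one individual
#'
#' Mean over three hemacytometer counts of count times the chamber
#' conversion factor (grains per microliter). The factor depends on the
#' chamber geometry (e.g. a 0.5-mm deep Nageotte chamber) and is a
#' configuration input.
#'
#' @param counts numeric vector of exactly 3 grain counts
#' @param factor chamber conversion factor, > 0
#' @return grains per microliter
#' @export
pollen_concentration <- function(counts, factor = 1) {
  if (length(counts) != 3L) {
    stop("expected exactly 3 hemacytometer counts, got ", length(counts))
  }
  if (!is.numeric(factor) || factor <= 0) {
    stop("chamber conversion factor must be positive")
  }
  mean(counts * factor)
}

#' Per-genotype summary of pollen measurements
#'
#' Genotype mean is the mean of per-individual averages; the standard
#' deviation is computed over all original raw measurements (sample sd,
#' n - 1) — the two-level convention used in pollen summary tables.
#'
#' @param measurements data.frame with columns `accession`, `genotype`,
#'   `value` (one row per raw measurement; per-individual averages may
#'   be supplied as single rows)
#' @return data.frame with `genotype`, `n_individuals`, `mean`
#'   (of per-individual means), `sd` (of raw measurements; `NA` for a
#'   single raw value)
#' @export
genotype_summary <- function(measurements) {
  stopifnot(all(c("accession", "genotype", "value") %in% names(measurements)))
  out <- lapply(split(measurements, measurements$genotype), function(d) {
    indiv <- tapply(d$value, d$accession, mean)
    data.frame(genotype = d$genotype[1],
               n_individuals = length(indiv),
               mean = mean(indiv),
               sd = stats::sd(d$value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-sample t test
#'
#' Thin wrapper over [stats::t.test()] defaulting to the Welch
#' (unequal-variance) variant; a Student (pooled-variance) variant is
#' provided. Degenerate input (zero variance in both groups with equal
#' means, where the test statistic is 0/0) returns t = 0, p = 1 with a
#' diagnostic note.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2
#' @param variant `"welch"` (default) or `"student"`
#' @return list with `t`, `df`, `p` and `note`
#' @export
two_sample_t <- function(group_a, group_b,
                         variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = NA_real_, p = 1,
                  note = "both groups constant with equal means"))
    }
    return(list(t = Inf * sign(mean(group_a) - mean(group_b)),
                df = NA_real_, p = 0,
                note = "both groups constant with different means"))
  }
  res <- stats::t.test(group_a, group_b,
                       var.equal = variant == "student")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, note = NA_character_)
}
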