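#' Round half away from zero
#'
#' Table-style rounding: 62.5 rounds to 63, unlike [round()]'s
#' round-half-even. Used for all integer percentages in frequency tables.
#'
#' @param x numeric vector
#' @param digits number of decimal places (default 0)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator
#'
#' @param count numerator
#' @param n denominator (must be > 0)
#' @param digits decimals kept in the raw percentage (default: exact)
#' @return list with `raw` (exact percentage) and `percent`
#'   (integer, rounded half up)
#' @export
percent_of <- function(count, n) {
  stopifnot(n > 0, count >= 0, count <= n)
  raw <- 100 * count / n
  list(raw = raw, percent = as.integer(round_half_up(raw)))
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored on exit so generators do not perturb sessions.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Oryza panel group labels in table order
#'
#' The closed set of population labels used throughout: the cultivated
#' groups (indica, aus, japonica), the US weedy groups (SH = straw hull,
#' BHA1/BHA2 = black hull awned subgroups, MX = weed x crop hybrids,
#' BRH = brown hull SH x BHA hybrids), wild (O. rufipogon/nivara) and
#' outgroup accessions.
#'
#' @return character vector of the ten group labels
#' @export
oryza_groups <- function() {
  c("indica", "aus", "japonica", "SH", "BHA1", "BHA2", "MX", "BRH",
    "wild", "outgroup")
}

# Table display order for population columns (outgroup excluded).
table1_group_order <- function() {
  c("indica", "aus", "japonica", "SH", "BHA1", "BHA2", "MX", "BRH", "wild")
}
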