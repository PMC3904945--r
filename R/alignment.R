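#' Coerce to an alignment character matrix
#'
#' Internal canonical form for aligned sequence sets: an upper-case
#' character matrix, one row per sequence, one column per alignment
#' column, gaps as "-", ambiguous bases as "N".
#'
#' @param x a character matrix, a named character vector of equal-length
#'   strings, or an [ape::DNAbin] matrix
#' @return character matrix with unique rownames
#' @export
as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) {
    x <- toupper(as.character(as.matrix(x)))
  } else if (is.character(x) && !is.matrix(x)) {
    if (length(x) == 0L) stop("empty alignment")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      bad <- names(x)[which(lens != lens[1])[1]]
      stop("aligned length mismatch for sequence '", bad, "'")
    }
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("seq", seq_along(x))
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- nm
  } else if (is.matrix(x) && is.character(x)) {
    x <- toupper(x)
    if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  } else {
    stop("cannot interpret input as an alignment")
  }
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty alignment")
  if (anyDuplicated(rownames(x))) stop("duplicate sequence names in alignment")
  x
}

#' Read a gapped FASTA alignment
#'
#' @param path FASTA file with aligned sequences ('-' gaps)
#' @return character matrix (see [as_alignment()])
#' @export
read_alignment <- function(path) {
  dna <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  as_alignment(dna)
}

#' Write an alignment to FASTA
#'
#' @param aln alignment (any form accepted by [as_alignment()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  seqs <- apply(aln, 1, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}
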