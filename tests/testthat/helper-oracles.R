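# Independent brute-force oracles, written as plain nested loops so they
# share no code path with the package implementations.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_diversity <- function(mat) {
  n <- nrow(mat)
  keep <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) keep[j] <- !any(mat[, j] == "-")
  sub <- mat[, keep, drop = FALSE]

  S <- 0L
  for (j in seq_len(ncol(sub))) {
    st <- character()
    for (i in seq_len(n)) {
      if (sub[i, j] %in% ORACLE_BASES) st <- c(st, sub[i, j])
    }
    if (length(unique(st)) >= 2L) S <- S + 1L
  }

  # pi: pairwise deletion over the full matrix
  pair_vals <- numeric()
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      d <- 0L; m <- 0L
      for (j in seq_len(ncol(mat))) {
        x <- mat[i, j]; y <- mat[k, j]
        if (x %in% ORACLE_BASES && y %in% ORACLE_BASES) {
          m <- m + 1L
          if (x != y) d <- d + 1L
        }
      }
      if (m > 0L) pair_vals <- c(pair_vals, d / m)
    }
  }
  pi_val <- if (length(pair_vals)) sum(pair_vals) / (n * (n - 1) / 2) else NaN

  a1 <- 0; a2 <- 0
  for (i in seq_len(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  L <- ncol(sub)
  theta <- if (L > 0L) S / (a1 * L) else NaN

  # mean pairwise difference count over gap-free columns
  tot <- 0L
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      for (j in seq_len(ncol(sub))) {
        x <- sub[i, j]; y <- sub[k, j]
        if (x %in% ORACLE_BASES && y %in% ORACLE_BASES && x != y) {
          tot <- tot + 1L
        }
      }
    }
  }
  kbar <- tot / (n * (n - 1) / 2)

  D <- NA_real_
  if (n >= 4L && S >= 1L) {
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    D <- (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  list(S = S, pi = pi_val, theta = theta, D = D)
}

# viable-gamete fraction by explicit enumeration of the 2 x 2 gamete
# combinations of a DPL double genotype
oracle_dpl_viable <- function(dpl1_pair, dpl2_pair) {
  viable <- 0L
  for (a in dpl1_pair) {
    for (b in dpl2_pair) {
      dead <- (a == "DPL1-K-") && (b == "DPL2-N-")
      if (!dead) viable <- viable + 1L
    }
  }
  viable / 4
}

# random gapped test alignment (uses the session RNG; callers set seeds)
random_alignment <- function(n, L, gap_prob = 0.05, n_prob = 0.02) {
  mat <- matrix(sample(ORACLE_BASES, n * L, replace = TRUE), nrow = n)
  # shared polymorphic columns
  n_poly <- sample.int(max(1L, L %/% 5), 1L)
  anc <- sample(ORACLE_BASES, L, replace = TRUE)
  for (j in seq_len(L)) mat[, j] <- anc[j]
  for (j in sample.int(L, n_poly)) {
    who <- sample.int(n, sample.int(n - 1L, 1L))
    mat[who, j] <- sample(setdiff(ORACLE_BASES, anc[j]), 1L)
  }
  mask <- matrix(runif(n * L) < gap_prob, nrow = n)
  mat[mask] <- "-"
  maskN <- matrix(runif(n * L) < n_prob, nrow = n)
  mat[maskN & !mask] <- "N"
  rownames(mat) <- paste0("t", seq_len(n))
  mat
}

# additive 4-taxon distance matrix for a chosen split, with the five
# branch lengths given; returns the matrix and the expected bipartition
additive_quartet <- function(split = c("AB", "AC", "AD"),
                             bl = c(1, 2, 3, 4, 5)) {
  split <- match.arg(split)
  taxa <- c("A", "B", "C", "D")
  # e1..e4 pendant edges in pair order, e5 internal
  pair1 <- switch(split, AB = c("A", "B"), AC = c("A", "C"),
                  AD = c("A", "D"))
  pair2 <- setdiff(taxa, pair1)
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  len <- c(setNames(bl[1:2], pair1), setNames(bl[3:4], pair2))
  for (x in taxa) for (y in taxa) {
    if (x == y) next
    same1 <- all(c(x, y) %in% pair1)
    same2 <- all(c(x, y) %in% pair2)
    D[x, y] <- len[[x]] + len[[y]] + if (same1 || same2) 0 else bl[5]
  }
  list(D = D, pair = sort(pair1))
}

# the split {pair}|{rest} of an unrooted 4-taxon tree, reported as the
# side containing taxon "A" (the canonical form used by additive_quartet)
quartet_split <- function(tree) {
  parts <- ape::prop.part(tree)
  for (p in parts) {
    tips <- sort(tree$tip.label[p])
    other <- sort(setdiff(tree$tip.label, tips))
    if (length(tips) == 2L && length(other) == 2L) {
      return(if ("A" %in% tips) tips else other)
    }
  }
  NULL
}
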