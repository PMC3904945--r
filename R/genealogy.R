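#' Kimura two-parameter distance between two aligned sequences
#'
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q), with P and Q the
#' transition and transversion proportions over the sites where both
#' sequences carry an unambiguous base (pairwise gap deletion).
#' Saturated pairs (1 - 2P - Q <= 0 or 1 - 2Q <= 0) raise a condition
#' of class `k2p_saturation`.
#'
#' @param a,b character vectors of equal aligned length
#' @return non-negative distance
#' @export
k2p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in aligned length")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% acgt & b %in% acgt
  n <- sum(ok)
  if (n == 0L) stop("no comparable gap-free sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop(structure(class = c("k2p_saturation", "error", "condition"),
                   list(message = sprintf(
                     "saturated distance (P = %.3f, Q = %.3f)", P, Q),
                     call = sys.call(-1))))
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param aln alignment (see [as_alignment()])
#' @param on_saturation `"na"` (default) records saturated pairs as
#'   `NA`; `"error"` re-raises
#' @return symmetric matrix with zero diagonal
#' @export
k2p_distance_matrix <- function(aln, on_saturation = c("na", "error")) {
  on_saturation <- match.arg(on_saturation)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(k2p_distance(aln[i, ], aln[j, ]),
                    k2p_saturation = function(e) {
                      if (on_saturation == "error") stop(e)
                      NA_real_
                    })
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration (via [ape::nj()]); on additive
#' matrices the recovered path lengths reproduce the input distances.
#' Negative branch lengths, which NJ can produce on noisy matrices, are
#' clamped to zero with the deficit transferred to the adjacent
#' branches of the same node so path lengths are approximately
#' preserved.
#'
#' @param D symmetric non-negative matrix with zero diagonal (labels as
#'   dimnames), at least 3 labels, no `NA`
#' @return unrooted `phylo` tree
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 labels")
  if (any(is.na(D))) stop("distance matrix contains NA (saturated pairs?)")
  if (!isTRUE(all.equal(D, t(D)))) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  tree <- ape::nj(as.dist(D))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == child)
    if (length(adj)) {
      tree$edge.length[adj] <- tree$edge.length[adj] + deficit / length(adj)
      tree$edge.length[adj][tree$edge.length[adj] < 0] <- 0
    }
  }
  tree
}

# Canonical bipartitions (internal, non-trivial) of an unrooted tree:
# each is the sorted tip-label set on the side not containing the
# alphabetically first label.
tree_bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- character()
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    other <- setdiff(labs, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (labs[1] %in% side) other else side
    out <- c(out, paste(canon, collapse = "|"))
  }
  unique(out)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the K2P/NJ tree from the full alignment, then resamples
#' alignment columns with replacement `B` times; the support of each
#' internal edge is the percentage of replicate trees containing the
#' same bipartition. Replicates whose distance matrix has a saturated
#' (undefined) pair are skipped and the denominator adjusted.
#' Deterministic under `seed`.
#'
#' @param aln alignment with >= 4 sequences
#' @param B number of bootstrap replicates (default 500)
#' @param seed integer RNG seed
#' @return list with `tree` (`phylo`, node labels carry integer
#'   supports; root label empty), `supports` (data.frame of bipartition
#'   and percent), `B` requested and `B_used` effective replicates
#' @export
bootstrap_supports <- function(aln, B = 500L, seed = 1L) {
  stopifnot(B >= 1L)
  aln <- as_alignment(aln)
  if (nrow(aln) < 4L) stop("need at least 4 sequences for internal edges")
  main <- nj_tree(k2p_distance_matrix(aln, on_saturation = "error"))
  bips <- tree_bipartitions(main)
  hits <- setNames(numeric(length(bips)), bips)
  used <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      rep_aln <- aln[, cols, drop = FALSE]
      D <- k2p_distance_matrix(rep_aln)
      if (any(is.na(D))) next  # saturated replicate skipped
      rep_bips <- tree_bipartitions(nj_tree(D))
      used <- used + 1L
      found <- bips %in% rep_bips
      hits[found] <- hits[found] + 1
    }
  })
  if (used == 0L) stop("all bootstrap replicates saturated")
  pct <- as.integer(round_half_up(100 * hits / used))
  supports <- data.frame(bipartition = bips, percent = pct,
                         stringsAsFactors = FALSE)
  tree <- attach_supports(main, supports)
  list(tree = tree, supports = supports, B = B, B_used = used)
}

# write bootstrap percentages into node labels of `tree`
attach_supports <- function(tree, supports) {
  labs <- sort(tree$tip.label)
  node_ids <- (length(tree$tip.label) + 1L):(length(tree$tip.label) + tree$Nnode)
  tree$node.label <- rep("", tree$Nnode)
  parts <- ape::prop.part(tree)
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    other <- setdiff(labs, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (labs[1] %in% side) other else side
    key <- paste(canon, collapse = "|")
    hit <- supports$percent[supports$bipartition == key]
    if (length(hit)) tree$node.label[k] <- as.character(hit[1])
  }
  tree
}

#' Write a support-labelled tree to Newick
#'
#' Bootstrap values below `min_support` are suppressed (left blank) on
#' rendering, the usual figure convention.
#'
#' @param tree `phylo` with node labels holding integer supports
#' @param path output file
#' @param min_support threshold below which labels are hidden (default 50)
#' @return `path`, invisibly
#' @export
write_support_newick <- function(tree, path, min_support = 50) {
  if (!is.null(tree$node.label)) {
    v <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label[!is.na(v) & v < min_support] <- ""
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
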