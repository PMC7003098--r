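#' Pairwise p-distances from a protein alignment
#'
#' Proportion of mismatching residues per pair. Under `pairwise_deletion`
#' (default) each pair is compared over the columns where neither row has a
#' gap or `X`; under `complete_deletion` every column containing a gap or
#' `X` in any row is removed first.
#'
#' @param aln an [aa_alignment()] with >= 2 rows.
#' @param gap_mode `"pairwise_deletion"` or `"complete_deletion"`.
#' @return symmetric `dist_matrix` (a numeric matrix with ids as dimnames
#'   and zero diagonal).
#' @export
p_distance <- function(aln, gap_mode = c("pairwise_deletion",
                                         "complete_deletion")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(aln, "aa_alignment"))
  if (nrow(aln) < 2) stop("need >= 2 rows", call. = FALSE)
  m <- unclass(aln)
  if (gap_mode == "complete_deletion") {
    keep <- colSums(m == "-" | m == "X") == 0
    m <- m[, keep, drop = FALSE]
  }
  ok <- m != "-" & m != "X"
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop("no comparable columns for pair ", rownames(m)[i], " / ",
           rownames(m)[j], call. = FALSE)
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
  }
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Poisson correction of p-distances
#'
#' Multiple-hit correction `d = -ln(1 - p)`, monotone in `p`.
#'
#' @param d a `dist_matrix` (or numeric matrix) of p-distances, all < 1.
#' @return corrected `dist_matrix`.
#' @export
poisson_correct <- function(d) {
  if (any(d >= 1)) stop("p-distances must be < 1 for Poisson correction",
                        call. = FALSE)
  out <- -log(1 - unclass(d))
  dimnames(out) <- dimnames(d)
  class(out) <- c("dist_matrix", class(out))
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-criterion. Ties in Q are broken by
#' the lowest `(i, j)` index pair in the current matrix (original input
#' order, merged nodes appended last), so the result is deterministic.
#' Negative branch lengths are clamped to zero; the total clamped deficit is
#' reported in attribute `"clamped"`.
#'
#' @param d symmetric non-negative matrix with ids as dimnames, zero
#'   diagonal, n >= 3.
#' @return unrooted binary `phylo` (attribute `"clamped"` = summed negative
#'   length removed).
#' @export
neighbor_joining <- function(d) {
  d <- unclass(d)
  if (is.null(dimnames(d)) || is.null(rownames(d)))
    stop("distance matrix needs ids as dimnames", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("non-symmetric input", call. = FALSE)
  n <- nrow(d)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  sub <- rownames(d)            # growing newick fragments
  names(sub) <- rownames(d)
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- c(0L, 0L); bq <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    vi <- clamp(0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(d[i, j] - (0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    new_sub <- paste0("(", sub[i], ":", format(vi, digits = 12), ",",
                      sub[j], ":", format(vj, digits = 12), ")")
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    d <- rbind(cbind(d[-c(i, j), -c(i, j), drop = FALSE],
                     du[-c(i, j)]),
               c(du[-c(i, j)], 0))
    nm <- c(sub[-c(i, j)], new_sub)
    sub <- nm
    rownames(d) <- colnames(d) <- paste0("#", seq_len(nrow(d)))
  }
  # final trifurcation
  v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", sub[1], ":", format(v1, digits = 12), ",",
                sub[2], ":", format(v2, digits = 12), ",",
                sub[3], ":", format(v3, digits = 12), ");")
  tr <- read_newick(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

# canonical keys of the non-trivial bipartitions of an unrooted tree
tree_splits <- function(tree) {
  nt <- n_tips(tree)
  anchor <- sort(tree$tip.label)[1]
  tips <- descendant_tips(tree)
  keys <- character(0)
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2]
    if (child <= nt) next               # pendant edge: trivial split
    side <- tips[[child]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > nt - 2) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Neighbor-joining with seeded column bootstrap
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times and reports, for each
#' internal bipartition of the point tree, the percentage of replicate trees
#' containing it. Supports annotate the point tree's internal `node.label`s
#' (the basal node of the unrooted representation is left blank). Rows are
#' sorted by id internally so results do not depend on input row order.
#'
#' @param aln an [aa_alignment()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param correction `"poisson"` (default) or `"p"` (uncorrected).
#' @param gap_mode passed to [p_distance()].
#' @return the point-estimate `phylo` with supports in `node.label`
#'   (percentages) and attribute `"splits"` (named support vector).
#' @export
nj_bootstrap <- function(aln, n_reps, seed,
                         correction = c("poisson", "p"),
                         gap_mode = "pairwise_deletion") {
  correction <- match.arg(correction)
  stopifnot(n_reps >= 1)
  aln <- aln[order(rownames(aln)), , drop = FALSE]
  class(aln) <- c("aa_alignment", class(aln))
  infer <- function(a) {
    d <- p_distance(a, gap_mode)
    if (correction == "poisson") d <- poisson_correct(d)
    neighbor_joining(d)
  }
  point <- infer(aln)
  target <- tree_splits(point)
  hits <- stats::setNames(numeric(length(target)), target)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      b <- aln[, cols, drop = FALSE]
      class(b) <- c("aa_alignment", class(b))
      bt <- tryCatch(infer(b), error = function(e) NULL)
      if (is.null(bt)) next
      found <- tree_splits(bt)
      hits[target %in% found] <- hits[target %in% found] + 1
    }
  })
  support <- 100 * hits / n_reps
  # map supports back onto internal nodes (edge above each internal node)
  nt <- n_tips(point)
  anchor <- sort(point$tip.label)[1]
  tips <- descendant_tips(point)
  lab <- rep("", point$Nnode)
  for (i in seq_len(nrow(point$edge))) {
    child <- point$edge[i, 2]
    if (child <= nt) next
    side <- tips[[child]]
    if (anchor %in% side) side <- setdiff(point$tip.label, side)
    key <- paste(sort(side), collapse = "\r")
    if (key %in% names(support))
      lab[child - nt] <- format(support[[key]], digits = 4)
  }
  point$node.label <- lab
  attr(point, "splits") <- support
  point
}
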