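## Representative sample selection: identity-by-state distances,
## neighbor-joining with deterministic tie-breaks, leaf ordering, stride
## selection.

#' Identity-by-state distance matrix
#'
#' For a pair of samples, over markers where both are called, each marker
#' contributes `2 - |g_i - g_j|` shared alleles (dosages in 0/1/2; het vs
#' het counts as 2 shared).  The distance is
#' `1 - shared / (2 * markers_valid)`, i.e. the mean per-allele
#' mismatch.  Not guaranteed metric; symmetric with zero diagonal by
#' construction.
#'
#' @param gm numeric matrix, samples x markers, entries 0/1/2 or NA.
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
ibsDistance <- function(gm) {
  if (nrow(gm) < 2) stop("need at least two samples")
  V <- !is.na(gm)
  X <- gm; X[!V] <- 0
  Vn <- matrix(as.numeric(V), nrow(gm))
  # sum |g_i - g_j| over jointly-called markers, via
  # |d| = d^2 - 2*[|d| == 2] and indicator matrix products
  Sab <- X %*% t(X)
  Sa2 <- (X * X) %*% t(Vn)
  D2 <- Sa2 + t(Sa2) - 2 * Sab
  I0 <- matrix(as.numeric(V & gm == 0), nrow(gm))
  I2 <- matrix(as.numeric(V & gm == 2), nrow(gm))
  E2 <- I0 %*% t(I2) + I2 %*% t(I0)
  M <- Vn %*% t(Vn)
  off <- row(M) != col(M)
  if (any(M[off] == 0)) {
    bad <- which(M == 0 & off, arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no called markers",
                 rownames(gm)[bad[1]], rownames(gm)[bad[2]]))
  }
  d <- (D2 - 2 * E2) / (2 * M)
  diag(d) <- 0
  dimnames(d) <- list(rownames(gm), rownames(gm))
  d
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Classical neighbor joining: iteratively join the pair (i, j) minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths `d(i,u) = d(i,j)/2 + (R_i - R_j)/(2(n-2))` and distance update
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2`.  Exact Q-ties are broken by
#' the lexicographically smallest pair of representative labels (the
#' smallest sample id contained in each subtree), making the tree a pure
#' function of the distance matrix regardless of input row order.
#' Negative branch lengths are retained, as in the classical algorithm.
#' Recovers additive (tree-realizable) distance matrices exactly.
#'
#' @param d symmetric distance matrix with unique sample ids as dimnames.
#' @return an `ape` `phylo` tree (unrooted, final join as the
#'   trifurcating root).
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least three samples")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique sample ids as dimnames")
  # order rows by label so ties resolve identically for permuted inputs
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]

  nodeId <- seq_len(n)                  # phylo tip numbers
  repLab <- labels                      # smallest contained sample id
  nextNode <- 2L * n - 2L               # internal ids assigned downward;
                                        # root ends up as n + 1
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on representative label pairs
    lo <- pmin(repLab[cand[, 1]], repLab[cand[, 2]])
    hi <- pmax(repLab[cand[, 1]], repLab[cand[, 2]])
    pick <- order(lo, hi)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    u <- nextNode; nextNode <- nextNode - 1L
    parent <- c(parent, u, u)
    child <- c(child, nodeId[i], nodeId[j])
    elen <- c(elen, li, lj)
    newD <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    nodeId <- c(nodeId[keep], u)
    repLab <- c(repLab[keep], min(repLab[c(i, j)]))
  }
  # final three-node star: closed-form lengths
  u <- nextNode
  stopifnot(u == n + 1L)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  parent <- c(parent, u, u, u)
  child <- c(child, nodeId[1], nodeId[2], nodeId[3])
  elen <- c(elen, la, lb, lc)

  tr <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                       edge.length = elen,
                       tip.label = labels,
                       Nnode = n - 2L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Deterministic ordered leaf list
#'
#' Depth-first traversal from the root (the final neighbor-joining join);
#' at every internal node, children are visited by ascending subtree leaf
#' count, ties broken by the smallest contained tip label.  Leaves that
#' are tree neighbors come out adjacent, so a fixed stride samples across
#' the whole tree.
#'
#' @param tree a `phylo` object.
#' @return character vector: a permutation of the tip labels.
#' @export
orderedLeaves <- function(tree) {
  n <- length(tree$tip.label)
  if (n == 1) return(tree$tip.label)
  if (is.null(tree$edge)) stop("not a phylo tree")
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  nNodes <- n + tree$Nnode
  leafCount <- integer(nNodes)
  minLab <- character(nNodes)
  postorder <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) {
      leafCount[v] <<- 1L
      minLab[v] <<- tree$tip.label[v]
    } else {
      for (c in ch) postorder(c)
      leafCount[v] <<- sum(leafCount[ch])
      minLab[v] <<- min(minLab[ch])
    }
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  postorder(root)
  out <- character(0)
  visit <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) {
      out[length(out) + 1L] <<- tree$tip.label[v]
    } else {
      for (c in ch[order(leafCount[ch], minLab[ch])]) visit(c)
    }
  }
  visit(root)
  out
}

#' Every-k-th selection from an ordered list
#'
#' Selects indices 1, 1+k, 1+2k, ... so an ordered list of n leaves yields
#' `floor((n-1)/k) + 1` representatives (1,000 leaves at the default
#' stride 8 give 125).
#'
#' @param ordered character vector (e.g. from [orderedLeaves()]).
#' @param k stride (default 8).
#' @param exclude optional ids to drop from the ordered list before
#'   selection (e.g. samples failing a relatedness screen).
#' @return selected ids in list order.
#' @export
strideSelect <- function(ordered, k = 8L, exclude = NULL) {
  stopifnot(k >= 1)
  if (!is.null(exclude)) ordered <- setdiff(ordered, exclude)
  if (length(ordered) == 0) return(character(0))
  ordered[seq(1L, length(ordered), by = k)]
}

#' One-call representative selection
#'
#' Convenience pipeline: IBS distances, neighbor-joining tree,
#' deterministic leaf ordering, stride selection.
#'
#' @param gm genotype dosage matrix (samples x markers).
#' @param k stride.
#' @param exclude optional sample ids to exclude before striding.
#' @return list with `selected`, `ordered`, `tree`, `dist`.
#' @export
selectRepresentatives <- function(gm, k = 8L, exclude = NULL) {
  d <- ibsDistance(gm)
  tr <- njTree(d)
  ord <- orderedLeaves(tr)
  list(selected = strideSelect(ord, k, exclude), ordered = ord,
       tree = tr, dist = d)
}
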