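## Hierarchical agglomerative clustering over an arbitrary dissimilarity
## matrix, with a fully deterministic tie rule so that taxonomies are
## reproducible: among equally close pairs, the pair whose clusters contain
## the smallest original indices merges first.
##
## Complete linkage takes the maximum inter-cluster dissimilarity. Ward
## linkage uses the Lance-Williams recurrence applied to the *squared* input
## dissimilarities (heights are therefore on the squared scale); on
## non-Euclidean dissimilarities such as DTW this is the usual heuristic
## extension of Ward's minimum-variance criterion.

#' Agglomerative clustering of a dissimilarity matrix
#'
#' @param D a `dist` object or symmetric numeric matrix with zero diagonal
#'   and non-negative entries, over at least 3 items.
#' @param linkage `"complete"` or `"ward"`.
#' @return List of class `curve_dendrogram` with `merge` (an
#'   `(n-1) x 2` matrix in `hclust` convention: negative entries are
#'   singletons, positive entries earlier merge rows), `height` (merge
#'   heights; squared-dissimilarity scale for Ward), `n`, and `linkage`.
#' @export
linkage_cluster <- function(D, linkage = c("complete", "ward")) {
  linkage <- match.arg(linkage)
  M <- as.matrix(D)
  n <- nrow(M)
  if (n < 3L) stop("need at least 3 items")
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-12)))
    stop("dissimilarity matrix must be symmetric")
  if (any(M < 0)) stop("dissimilarity matrix must be non-negative")
  if (any(diag(M) != 0)) stop("dissimilarity matrix must have zero diagonal")

  W <- if (linkage == "ward") M^2 else M
  diag(W) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  rep_idx <- seq_len(n)        # smallest original member of each slot
  node_id <- -seq_len(n)       # hclust ids: negative singleton, positive merge

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    Wa <- W[act, act, drop = FALSE]
    h <- min(Wa)
    cand <- which(Wa == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie rule: lexicographically smallest (rep_i, rep_j)
    ri <- rep_idx[act[cand[, 1L]]]
    rj <- rep_idx[act[cand[, 2L]]]
    lo <- pmin(ri, rj); hi <- pmax(ri, rj)
    pick <- order(lo, hi)[1L]
    i <- act[cand[pick, 1L]]; j <- act[cand[pick, 2L]]
    if (rep_idx[j] < rep_idx[i]) { tmp <- i; i <- j; j <- tmp }

    merge[step, ] <- sort(c(node_id[i], node_id[j]))
    height[step] <- h

    others <- setdiff(act, c(i, j))
    if (length(others)) {
      if (linkage == "complete") {
        newd <- pmax(W[i, others], W[j, others])
      } else {
        ni <- size[i]; nj <- size[j]; nk <- size[others]
        newd <- ((ni + nk) * W[i, others] + (nj + nk) * W[j, others] -
                   nk * W[i, j]) / (ni + nj + nk)
      }
      W[i, others] <- newd
      W[others, i] <- newd
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    node_id[i] <- step
    # rep_idx[i] already the smaller of the two representatives
  }
  structure(list(merge = merge, height = height, n = n, linkage = linkage),
            class = "curve_dendrogram")
}

#' Cut a dendrogram into k clusters
#'
#' Applies the first `n - k` merges of the agglomeration, so that successive
#' cuts are nested by construction: the k-partition is always obtained by
#' merging exactly two clusters of the (k+1)-partition.
#'
#' Cluster indices are renumbered 1..k by each cluster's smallest original
#' member, making labels deterministic.
#'
#' @param dendro a [linkage_cluster()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster indices, one per original item.
#' @export
cut_dendrogram <- function(dendro, k) {
  n <- dendro$n
  if (k < 1L || k > n) stop("k out of range")
  comp <- seq_len(n)                 # component id per item
  node_members <- vector("list", n - 1L)
  nsteps <- n - k
  if (nsteps > 0L) {
    for (step in seq_len(nsteps)) {
      a <- dendro$merge[step, 1L]; b <- dendro$merge[step, 2L]
      mem_a <- if (a < 0L) -a else node_members[[a]]
      mem_b <- if (b < 0L) -b else node_members[[b]]
      members <- c(mem_a, mem_b)
      node_members[[step]] <- members
      comp[members] <- min(comp[members])
    }
  }
  # renumber by smallest member
  reps <- sort(unique(comp))
  match(comp, reps)
}
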