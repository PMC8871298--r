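# Independent reference implementations used as oracles. They deliberately
# share no code with the package: top-down memoized recursion for DTW, direct
# recomputation of inter-cluster distances from the original matrix for the
# agglomeration, and a plain-loop ReliefF.

dtw_oracle <- function(x, y) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- abs(x[i] - y[j]) + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[[key]] <- v
    v
  }
  rec(length(x), length(y))
}

# Naive O(n^3) agglomeration: every step recomputes all inter-cluster
# distances from the original matrix. Complete linkage is the max over cross
# pairs; Ward is the explicit pairwise-sum (ESS) formula on squared
# dissimilarities. Tie rule: lexicographically smallest pair of smallest
# original members.
naive_linkage_oracle <- function(M, linkage) {
  n <- nrow(M)
  M2 <- M^2
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  hts <- numeric(n - 1L)
  cdist <- function(A, B) {
    if (linkage == "complete") return(max(M[A, B]))
    nA <- length(A); nB <- length(B)
    cross <- sum(M2[A, B]) / (nA * nB)
    wA <- sum(M2[A, A]) / (2 * nA^2)
    wB <- sum(M2[B, B]) / (2 * nB^2)
    2 * (nA * nB / (nA + nB)) * (cross - wA - wB)
  }
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- cdist(clusters[[i]], clusters[[j]])
        key <- sort(c(clusters[[i]][1L], clusters[[j]][1L]))
        better <- is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
                (key[1L] == best$key[1L] && key[2L] < best$key[2L])))
        if (better) best <- list(d = d, i = i, j = j, key = key)
      }
    }
    merges[s, ] <- sort(c(ids[best$i], ids[best$j]))
    hts[s] <- best$d
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    ids[best$i] <- s
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  list(merge = merges, height = hts)
}

# Plain-loop ReliefF over all instances; mirrors the published update rule
# with Manhattan neighbor search and (distance, index) tie-breaking.
relieff_oracle <- function(features, labels, k = 10L) {
  features <- as.data.frame(features)
  n <- nrow(features)
  labels <- as.character(labels)
  priors <- table(labels) / n
  diffs <- function(f, i, j) {
    col <- features[[f]]
    if (is.numeric(col)) {
      rng <- max(col) - min(col)
      if (rng <= 0) 0 else abs(col[i] - col[j]) / rng
    } else {
      if (as.character(col[i]) == as.character(col[j])) 0 else 1
    }
  }
  inst_dist <- function(i, j)
    sum(vapply(names(features), function(f) diffs(f, i, j), numeric(1)))
  W <- setNames(numeric(ncol(features)), names(features))
  for (i in seq_len(n)) {
    for (cl in names(priors)) {
      pool <- setdiff(which(labels == cl), i)
      if (!length(pool)) next
      dd <- vapply(pool, function(j) inst_dist(i, j), numeric(1))
      nb <- pool[order(dd, pool)][seq_len(min(k, length(pool)))]
      w <- if (cl == labels[i]) -1 else priors[[cl]] / (1 - priors[[labels[i]]])
      for (f in names(features)) {
        for (j in nb) W[f] <- W[f] + w * diffs(f, i, j) / (n * k)
      }
    }
  }
  W
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# random symmetric dissimilarity matrix with zero diagonal
random_dissimilarity <- function(n) {
  P <- matrix(runif(n * 3), n)
  as.matrix(dist(P))
}
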