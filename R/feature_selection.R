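## Filter feature selection: Information Gain, symmetrical uncertainty and
## ReliefF, applied identically to nominal taxonomy-membership columns and
## (after equal-frequency discretization, for the entropy-based filters) to
## numeric common-feature columns.

entropy_bits <- function(x) {
  p <- table(x)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Equal-frequency discretization
#'
#' Bins a numeric vector into (at most) `bins` categories at its empirical
#' quantiles. Breaks computed on training data can be reused on new data via
#' the `breaks` attribute.
#'
#' @param x numeric vector.
#' @param bins target number of bins (default 10).
#' @param breaks optional pre-computed break points.
#' @return Factor with a `breaks` attribute.
#' @export
discretize_ef <- function(x, bins = 10L, breaks = NULL) {
  if (is.null(breaks)) {
    qs <- quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                   names = FALSE, type = 7)
    breaks <- unique(qs)
    if (length(breaks) < 2L) breaks <- c(breaks - 0.5, breaks + 0.5)
  }
  f <- cut(x, breaks = breaks, include.lowest = TRUE)
  # values outside the training range fall into the nearest edge bin
  f[is.na(f) & x < breaks[1L]] <- levels(f)[1L]
  f[is.na(f)] <- levels(f)[length(levels(f))]
  attr(f, "breaks") <- breaks
  f
}

#' Information gain of a nominal feature about the class
#'
#' `IG = H(class) - H(class | feature)` in bits. Numeric features must be
#' discretized first (see [discretize_ef()]).
#'
#' @param feature nominal vector (factor or character).
#' @param labels class labels (at least 2 distinct values).
#' @return Non-negative scalar, in bits.
#' @export
info_gain <- function(feature, labels) {
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (length(feature) != length(labels)) stop("length mismatch")
  h_class <- entropy_bits(labels)
  n <- length(labels)
  h_cond <- 0
  for (v in unique(feature)) {
    idx <- feature == v
    h_cond <- h_cond + sum(idx) / n * entropy_bits(labels[idx])
  }
  h_class - h_cond
}

#' Symmetrical uncertainty between a feature and the class
#'
#' `SU = 2 IG / (H(feature) + H(class))`, a normalized mutual information in
#' `[0, 1]`; defined as 0 when both entropies vanish.
#'
#' @inheritParams info_gain
#' @return Scalar in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(feature, labels) {
  hf <- entropy_bits(feature)
  hc <- entropy_bits(labels)
  if (hf + hc == 0) return(0)
  2 * info_gain(feature, labels) / (hf + hc)
}

# ReliefF attribute difference: 0/1 for nominal, range-scaled absolute
# difference for numeric (0 when the training range is degenerate).
relief_diff <- function(col, i, j, rng) {
  if (is.numeric(col)) {
    if (rng <= 0) return(rep(0, length(j)))
    abs(col[i] - col[j]) / rng
  } else {
    as.numeric(col[i] != col[j])
  }
}

#' ReliefF feature weights
#'
#' Standard ReliefF: every instance (no subsampling, for determinism) looks
#' up its `k_neighbors` nearest hits and, per opposite class, nearest misses;
#' feature weights decrease with near-hit differences and increase with
#' class-prior-weighted near-miss differences. Distances for the neighbor
#' search are Manhattan sums of the per-feature differences; neighbor ties
#' break by instance index.
#'
#' @param features data.frame of nominal (factor) and/or numeric columns.
#' @param labels class labels; every class needs at least 2 members.
#' @param k_neighbors neighbors per class (default 10), capped at
#'   availability.
#' @return Named numeric vector of weights, one per column.
#' @export
relieff <- function(features, labels, k_neighbors = 10L) {
  features <- as.data.frame(features)
  n <- nrow(features)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L)) stop("every class needs at least 2 members")
  priors <- tab / n
  p <- ncol(features)
  rngs <- vapply(features, function(col)
    if (is.numeric(col)) diff(range(col)) else NA_real_, numeric(1))

  # full pairwise instance distance (Manhattan over per-feature diffs)
  Dm <- matrix(0, n, n)
  for (f in seq_len(p)) {
    col <- features[[f]]
    if (is.numeric(col)) {
      if (rngs[f] > 0) Dm <- Dm + abs(outer(col, col, "-")) / rngs[f]
    } else {
      Dm <- Dm + outer(as.character(col), as.character(col), "!=")
    }
  }

  W <- setNames(numeric(p), names(features))
  mk <- n * k_neighbors
  for (i in seq_len(n)) {
    for (cl in names(tab)) {
      pool <- which(labels == cl & seq_len(n) != i)
      if (!length(pool)) next
      ord <- pool[order(Dm[i, pool], pool)]
      nb <- head(ord, k_neighbors)
      wgt <- if (cl == labels[i]) -1 else priors[[cl]] / (1 - priors[[labels[i]]])
      # average over the k requested slots even when fewer neighbors exist
      for (f in seq_len(p)) {
        d <- relief_diff(features[[f]], i, nb, rngs[f])
        W[f] <- W[f] + wgt * sum(d) / mk
      }
    }
  }
  W
}

#' Score every feature column of a table
#'
#' @param table feature data.frame with `measurement_id` and `label` columns
#'   followed by feature columns.
#' @param method `"infogain"`, `"symm_unc"` or `"relieff"`.
#' @param bins discretization bins for numeric columns under the
#'   entropy-based methods.
#' @param k_neighbors passed to [relieff()].
#' @return data.frame `feature_id`, `method`, `score`.
#' @export
score_features <- function(table, method = c("infogain", "symm_unc", "relieff"),
                           bins = 10L, k_neighbors = 10L) {
  method <- match.arg(method)
  labels <- table$label
  feats <- table[, setdiff(names(table), c("measurement_id", "label")),
                 drop = FALSE]
  if (method == "relieff") {
    sc <- relieff(feats, labels, k_neighbors = k_neighbors)
  } else {
    fun <- if (method == "infogain") info_gain else symmetrical_uncertainty
    sc <- vapply(feats, function(col) {
      if (is.numeric(col)) col <- discretize_ef(col, bins = bins)
      fun(col, labels)
    }, numeric(1))
  }
  data.frame(feature_id = names(feats), method = method, score = unname(sc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select features from a score table
#'
#' @param scores data.frame from [score_features()].
#' @param policy `"top_m"` keeps the `m` highest-scoring features (ties break
#'   lexicographically by feature id); `"positive"` keeps features with
#'   score > 0 (meaningful for the entropy-based filters).
#' @param m budget for `top_m` (default 26, one column per sensor of the
#'   full array).
#' @return Character vector of selected feature ids.
#' @export
select_features <- function(scores, policy = c("top_m", "positive"), m = 26L) {
  policy <- match.arg(policy)
  if (policy == "positive") {
    sel <- scores$feature_id[scores$score > 0]
    sel <- sort(sel)
  } else {
    ord <- order(-scores$score, scores$feature_id)
    sel <- scores$feature_id[head(ord, m)]
  }
  if (!length(sel)) stop("no informative features")
  sel
}
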