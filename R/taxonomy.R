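## Shape taxonomies: the per-sensor nested family of curve-shape clusters
## obtained by cutting one dendrogram at k = 2..10, each cluster represented
## by its characteristic curve (the pointwise mean of its members).

#' Fit a shape taxonomy to a panel of curves
#'
#' Clusters the preprocessed response curves of one sensor hierarchically
#' under the chosen dissimilarity and linkage, cuts the dendrogram at every
#' `k` in `k_range`, and stores for each cut the cluster assignment and the
#' characteristic (pointwise-mean) curve of every cluster.
#'
#' @param x a [curve_panel()] or a numeric matrix with one curve per row.
#' @param distance `"euclidean"` or `"dtwarp"`.
#' @param linkage `"complete"` or `"ward"`.
#' @param k_range integer vector of cut sizes (default `2:10`). Cuts larger
#'   than the number of curves are omitted with a warning.
#' @param band optional Sakoe-Chiba band for DTW.
#' @param sensor_id identifier stored on the object (taken from the panel if
#'   one is given).
#' @return An object of class `shape_taxonomy` with the dendrogram
#'   (`merge`, `height`), the training `measurement_ids`, and `levels`: one
#'   entry per cut `k` holding `assignment` (named integer vector) and
#'   `centroids` (k x T matrix of characteristic curves).
#' @seealso [predict.shape_taxonomy()], [membership_feature_table()]
#' @export
shape_taxonomy <- function(x, distance = c("euclidean", "dtwarp"),
                           linkage = c("complete", "ward"),
                           k_range = 2:10, band = NULL, sensor_id = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (inherits(x, "curve_panel")) {
    if (is.null(sensor_id)) sensor_id <- x$sensor_id
    curves <- x$curves
  } else {
    curves <- as.matrix(x)
    if (is.null(sensor_id)) sensor_id <- "sensor"
  }
  n <- nrow(curves)
  ids <- rownames(curves)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  k_range <- sort(unique(as.integer(k_range)))
  if (n < max(2L, min(k_range)))
    stop("panel has fewer curves than the smallest requested cut")

  D <- curve_dist(curves, distance = distance, band = band)
  dendro <- linkage_cluster(D, linkage = linkage)
  if (all(dendro$height == 0))
    warning("degenerate merges: all curves identical (all heights 0)")

  feasible <- k_range[k_range <= n]
  if (length(feasible) < length(k_range))
    warning("omitting cut(s) k > number of curves: ",
            paste(setdiff(k_range, feasible), collapse = ", "))
  levels <- lapply(feasible, function(k) {
    cl <- cut_dendrogram(dendro, k)
    centroids <- t(vapply(seq_len(k), function(g)
      colMeans(curves[cl == g, , drop = FALSE]), numeric(ncol(curves))))
    list(k = k, assignment = setNames(cl, ids), centroids = centroids)
  })
  names(levels) <- as.character(feasible)

  structure(list(sensor_id = sensor_id, distance = distance,
                 linkage = linkage, band = band,
                 merge = dendro$merge, height = dendro$height,
                 n = n, T = ncol(curves), k_range = feasible,
                 measurement_ids = ids, levels = levels),
            class = "shape_taxonomy")
}

#' Assign a curve to its nearest characteristic curve
#'
#' Membership of an unseen curve at one taxonomy level: the index of the
#' nearest characteristic curve under the taxonomy's own dissimilarity, ties
#' broken toward the lower cluster index. Uses only training-derived
#' artifacts, so it is leakage-safe for held-out data.
#'
#' @param curve numeric vector of length `T` (the taxonomy's curve length).
#' @param taxonomy a [shape_taxonomy()].
#' @param k taxonomy level (must be one of the fitted cuts).
#' @return Cluster index in `1..k`.
#' @export
assign_membership <- function(curve, taxonomy, k) {
  lev <- taxonomy$levels[[as.character(k)]]
  if (is.null(lev)) stop("no level k = ", k, " in this taxonomy")
  if (length(curve) != taxonomy$T)
    stop("curve length ", length(curve), " does not match taxonomy T = ",
         taxonomy$T)
  d <- apply(lev$centroids, 1L, function(cc) {
    if (taxonomy$distance == "euclidean") euclidean_distance(curve, cc)
    else dtw_distance(curve, cc, band = taxonomy$band)
  })
  which.min(d) # which.min takes the first (lowest-index) minimum
}

#' Predict taxonomy memberships for new curves
#'
#' @param object a [shape_taxonomy()].
#' @param newdata numeric matrix of curves (rows) or a single curve vector.
#' @param k one fitted level, or `NULL` (default) for all levels.
#' @param ... unused.
#' @return If `k` is given, an integer vector of memberships; otherwise an
#'   integer matrix with one column per fitted level, named `k<k>`.
#' @export
predict.shape_taxonomy <- function(object, newdata, k = NULL, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  ks <- if (is.null(k)) object$k_range else as.integer(k)
  out <- vapply(ks, function(kk)
    apply(newdata, 1L, assign_membership, taxonomy = object, k = kk),
    integer(nrow(newdata)))
  out <- matrix(out, nrow = nrow(newdata),
                dimnames = list(rownames(newdata), paste0("k", ks)))
  if (!is.null(k) && length(k) == 1L) out[, 1L] else out
}

#' @export
print.shape_taxonomy <- function(x, ...) {
  cat(sprintf("shape_taxonomy '%s': %d curves x %d points, %s distance, %s linkage\n",
              x$sensor_id, x$n, x$T, x$distance, x$linkage))
  cat("  cuts: k =", paste(x$k_range, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.shape_taxonomy <- function(object, ...) {
  sizes <- lapply(object$levels, function(l) as.integer(table(l$assignment)))
  cat(sprintf("shape_taxonomy '%s' (%s distance, %s linkage)\n",
              object$sensor_id, object$distance, object$linkage))
  for (nm in names(sizes))
    cat(sprintf("  k=%s: cluster sizes %s\n", nm,
                paste(sizes[[nm]], collapse = "/")))
  invisible(sizes)
}

#' Plot the characteristic curves of one taxonomy level
#'
#' @param x a [shape_taxonomy()].
#' @param k level to plot (default: the smallest fitted cut).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.shape_taxonomy <- function(x, k = min(x$k_range), ...) {
  lev <- x$levels[[as.character(k)]]
  if (is.null(lev)) stop("no level k = ", k)
  matplot(t(lev$centroids), type = "l", lty = 1,
          xlab = "time point", ylab = "normalized response",
          main = sprintf("%s: %d characteristic curves", x$sensor_id, k), ...)
  invisible(x)
}

#' Fit taxonomies for every sensor panel
#'
#' @param panels named list of row-aligned [curve_panel()] objects.
#' @param ... passed to [shape_taxonomy()].
#' @return Named list of [shape_taxonomy()] objects.
#' @export
build_taxonomies <- function(panels, ...) {
  lapply(panels, shape_taxonomy, ...)
}

#' Encode taxonomy memberships as a nominal feature table
#'
#' One nominal column per (sensor, cut) pair, named `<sensor>_k<k>`; the
#' value is the cluster index of the measurement at that cut. Rows the
#' taxonomy was trained on use their stored assignments; other rows (e.g.
#' held-out measurements) are assigned to the nearest characteristic curve
#' via [assign_membership()].
#'
#' @param taxonomies named list of [shape_taxonomy()] objects, one per
#'   sensor (names must cover the panel names).
#' @param panels named list of row-aligned [curve_panel()] objects.
#' @param labels named character vector of class labels.
#' @return data.frame: `measurement_id`, `label`, then factor columns with
#'   levels `1..k`.
#' @export
membership_feature_table <- function(taxonomies, panels, labels) {
  ids <- assert_aligned_panels(panels)
  if (!all(ids %in% names(labels)))
    stop("label missing for measurement(s): ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  missing_tax <- setdiff(names(panels), names(taxonomies))
  if (length(missing_tax))
    stop("missing taxonomy for sensor(s): ",
         paste(missing_tax, collapse = ", "))
  cols <- list()
  for (sid in names(panels)) {
    tax <- taxonomies[[sid]]
    p <- panels[[sid]]
    for (k in tax$k_range) {
      lev <- tax$levels[[as.character(k)]]
      v <- integer(length(ids))
      stored <- ids %in% names(lev$assignment)
      v[stored] <- lev$assignment[ids[stored]]
      if (any(!stored))
        v[!stored] <- apply(p$curves[!stored, , drop = FALSE], 1L,
                            assign_membership, taxonomy = tax, k = k)
      cols[[paste0(sid, "_k", k)]] <- factor(v, levels = seq_len(k))
    }
  }
  data.frame(measurement_id = ids, label = unname(labels[ids]), cols,
             stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
}
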