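## Curve dissimilarities: pointwise Euclidean distance and dynamic time
## warping (DTWARP). DTW extends the pointwise comparison by aligning each
## point with one or more points of the other series, absorbing delays and
## speed differences in the sensor reaction.

#' Euclidean distance between two equal-length series
#'
#' `sqrt(sum((x - y)^2))` over the paired time points.
#'
#' @param x,y numeric vectors of equal length.
#' @return Non-negative scalar; zero iff `x == y`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  sqrt(sum((x - y)^2))
}

#' Dynamic-time-warping distance between two series
#'
#' Minimum total cost over monotone alignment paths with steps (1,0), (0,1)
#' and (1,1), local cost `|x_i - y_j|`, unnormalized path sum. An optional
#' Sakoe-Chiba band restricts the alignment to `|i - j| <= band`.
#'
#' @param x,y numeric vectors (non-empty; lengths may differ).
#' @param band non-negative integer band half-width, or `NULL` (default) for
#'   an unconstrained alignment. Must be at least `abs(length(x) - length(y))`.
#' @return Non-negative scalar; symmetric; zero when `x == y`.
#' @export
dtw_distance <- function(x, y, band = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sequence")
  b <- if (is.null(band)) -1L else as.integer(band)
  if (b >= 0L && b < abs(length(x) - length(y)))
    stop("band narrower than the length difference")
  .dtw_cost(as.numeric(x), as.numeric(y), b)
}

#' Pairwise curve dissimilarities for a panel
#'
#' @param curves numeric matrix, one curve per row.
#' @param distance `"euclidean"` or `"dtwarp"`.
#' @param band optional Sakoe-Chiba band for DTW.
#' @return A `dist` object over the rows.
#' @export
curve_dist <- function(curves, distance = c("euclidean", "dtwarp"),
                       band = NULL) {
  distance <- match.arg(distance)
  curves <- as.matrix(curves)
  if (distance == "euclidean") return(stats::dist(curves))
  b <- if (is.null(band)) -1L else as.integer(band)
  d <- .dtw_pdist(curves, b)
  attributes(d) <- list(Size = nrow(curves), Labels = rownames(curves),
                        Diag = FALSE, Upper = FALSE, method = "dtwarp",
                        class = "dist")
  d
}
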