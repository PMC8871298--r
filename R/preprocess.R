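## Preprocessing: raw traces -> equal-length, baseline-normalized, denoised
## curve panels, with multivariate outlier screening on PCA score and
## orthogonal distances.

#' Equalize the lengths of a set of series
#'
#' Some sensors record a few extra time points at the beginning of a
#' measurement. The common length is the minimum across inputs, and extra
#' points are removed from the *start* of longer series so that the
#' stabilized tail of the response is preserved (`trim = "head"`). A
#' symmetric trim that removes points from both ends is available.
#'
#' @param traces list of numeric vectors.
#' @param trim `"head"` (default) or `"symmetric"`.
#' @param min_length shortest acceptable series (default 10).
#' @return List of numeric vectors, all of the same length.
#' @export
equalize_lengths <- function(traces, trim = c("head", "symmetric"),
                             min_length = 10L) {
  trim <- match.arg(trim)
  stopifnot(is.list(traces), length(traces) > 0L)
  lens <- lengths(traces)
  if (any(lens < min_length))
    stop("series shorter than the minimum length (", min_length, ")")
  T <- min(lens)
  lapply(traces, function(x) {
    extra <- length(x) - T
    if (extra == 0L) return(x)
    if (trim == "head") {
      x[(extra + 1L):length(x)]
    } else {
      lead <- extra %/% 2L # odd surplus: one more point off the head
      x[(extra - lead + 1L):(length(x) - lead)]
    }
  })
}

#' Normalize a breath curve against the stabilized baseline tail
#'
#' The reference is the mean of the last `b_tail` room-air baseline values,
#' i.e. the sensor level once the response to ambient air has stabilized.
#' Ratio mode (the chemiresistive R/R0 convention, default) divides by the
#' reference; difference mode subtracts it.
#'
#' @param breath numeric breath-phase values.
#' @param baseline numeric baseline-phase values (length >= `b_tail`).
#' @param mode `"ratio"` or `"difference"`.
#' @param b_tail number of final baseline points averaged (default 10).
#' @param epsilon smallest usable |reference| in ratio mode.
#' @return Unitless numeric vector, same length as `breath`.
#' @export
normalize_to_baseline <- function(breath, baseline,
                                  mode = c("ratio", "difference"),
                                  b_tail = 10L, epsilon = 1e-9) {
  mode <- match.arg(mode)
  if (length(baseline) < b_tail)
    stop("baseline has fewer than b_tail = ", b_tail, " points")
  r <- mean(tail(baseline, b_tail))
  if (mode == "ratio") {
    if (abs(r) <= epsilon) stop("degenerate baseline")
    breath / r
  } else {
    breath - r
  }
}

#' Running median filter with replicate padding
#'
#' @param x numeric vector.
#' @param window odd window width; `window = 1` is the identity.
#' @return Filtered vector, same length as `x`; edges are handled by
#'   replicating the first/last value.
#' @export
median_filter <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 1L || window > length(x)) stop("window out of range")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  vapply(seq_along(x), function(i) median(xp[i:(i + window - 1L)]), numeric(1))
}

#' PCA score/orthogonal-distance outlier detection
#'
#' Observations (rows) are centred and projected onto the principal
#' components retaining the smallest number of components that explain at
#' least `var_explained` of the variance (capped at `nrow - 1`). The score
#' distance (SD) is the Mahalanobis distance within the retained score space;
#' the orthogonal distance (OD) is the Euclidean norm of the residual outside
#' it. Cutoffs come from scaled chi-squared distributions fitted to the
#' squared distances by moment matching (mean m, variance v give scale
#' v/(2m) and m degrees of freedom 2m^2/v), evaluated at quantile
#' `1 - alpha`. A row is flagged when SD or OD exceeds its cutoff.
#'
#' To resist masking (gross outliers inflating the component model and their
#' own cutoffs), the model and cutoffs are re-estimated on the rows not
#' currently flagged, scoring all rows against the clean model, until the
#' flag set is stable (at most `max_iter` refits).
#'
#' @param x numeric matrix, measurements in rows (>= 10 rows).
#' @param alpha tail probability in (0, 0.5); default 0.01.
#' @param var_explained retained variance fraction; default 0.95.
#' @param row_ids optional row identifiers.
#' @param max_iter maximum model refits (default 10).
#' @return data.frame with columns `measurement_id`, `score_distance`,
#'   `orthogonal_distance`, `sd_cutoff`, `od_cutoff`, `flagged`.
#' @export
detect_outliers <- function(x, alpha = 0.01, var_explained = 0.95,
                            row_ids = rownames(x), max_iter = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 rows for outlier detection")
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must lie in (0, 0.5)")
  if (is.null(row_ids)) row_ids <- as.character(seq_len(n))

  chi_cutoff2 <- function(u2) {
    # scaled chi-squared by moment matching: mean m = s*df, var v = 2*s^2*df
    m <- mean(u2); v <- var(u2)
    if (!is.finite(v) || v <= .Machine$double.eps || m <= .Machine$double.eps)
      return(Inf) # degenerate sample: nothing flagged on this distance
    s <- v / (2 * m); df <- 2 * m^2 / v
    s * qchisq(1 - alpha, df)
  }

  score_against <- function(clean) {
    xcl <- x[clean, , drop = FALSE]
    ctr <- colMeans(xcl)
    xc_cl <- sweep(xcl, 2L, ctr)
    sv <- svd(xc_cl, nu = 0, nv = min(nrow(xcl), ncol(x)))
    ev <- sv$d^2 / (nrow(xcl) - 1)
    if (sum(ev) <= .Machine$double.eps) stop("no variation")
    cum <- cumsum(ev) / sum(ev)
    a <- min(which(cum >= var_explained), nrow(xcl) - 1L)
    V <- sv$v[, seq_len(a), drop = FALSE]
    xc_all <- sweep(x, 2L, ctr)
    scores <- xc_all %*% V
    sd2 <- rowSums(sweep(scores^2, 2,
                         pmax(ev[seq_len(a)], .Machine$double.eps), "/"))
    od2 <- rowSums((xc_all - scores %*% t(V))^2)
    list(sd2 = sd2, od2 = od2,
         sd_cut2 = chi_cutoff2(sd2[clean]),
         od_cut2 = chi_cutoff2(od2[clean]))
  }

  # Gross-error prescreen: rows whose squared distance from the column-median
  # vector exceeds 25x the median distance are kept out of the *initial*
  # clean set, so that gross outliers cannot own the component model and mask
  # themselves. Gross errors are assumed rare: if more than 20% of rows look
  # far, that is structure (e.g. a distinct curve-shape group), not error,
  # and no row is prescreened. The chi-squared detector makes all decisions.
  u <- rowSums(sweep(x, 2L, apply(x, 2L, median))^2)
  cand <- u > 25 * median(u)
  clean <- if (any(cand) && sum(cand) <= 0.2 * n && sum(!cand) >= 10L) !cand
           else rep(TRUE, n)
  fit <- score_against(clean)
  for (it in seq_len(max_iter)) {
    flagged <- fit$sd2 > fit$sd_cut2 | fit$od2 > fit$od_cut2
    new_clean <- !flagged
    # trimming more than 20% of rows would be model collapse, not cleaning
    if (sum(flagged) > 0.2 * n || sum(new_clean) < 10L ||
        identical(new_clean, clean)) break
    clean <- new_clean
    fit <- score_against(clean)
  }

  data.frame(
    measurement_id = row_ids,
    score_distance = sqrt(fit$sd2),
    orthogonal_distance = sqrt(fit$od2),
    sd_cutoff = sqrt(fit$sd_cut2),
    od_cutoff = sqrt(fit$od_cut2),
    flagged = fit$sd2 > fit$sd_cut2 | fit$od2 > fit$od_cut2,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Construct a curve panel
#'
#' Equal-length, normalized curves for one sensor across all measurements.
#'
#' @param sensor_id sensor identifier.
#' @param curve_matrix measurements x T numeric matrix.
#' @param measurement_ids row identifiers, aligned to rows.
#' @return Object of class `curve_panel`.
#' @export
curve_panel <- function(sensor_id, curve_matrix, measurement_ids) {
  curve_matrix <- as.matrix(curve_matrix)
  stopifnot(nrow(curve_matrix) == length(measurement_ids),
            all(is.finite(curve_matrix)))
  rownames(curve_matrix) <- measurement_ids
  structure(list(sensor_id = sensor_id, curves = curve_matrix,
                 measurement_ids = as.character(measurement_ids),
                 T = ncol(curve_matrix)),
            class = "curve_panel")
}

#' @export
print.curve_panel <- function(x, ...) {
  cat(sprintf("curve_panel '%s': %d measurements x %d time points\n",
              x$sensor_id, nrow(x$curves), x$T))
  invisible(x)
}

#' Default preprocessing configuration
#'
#' @param trim head or symmetric length trimming.
#' @param normalize ratio (R/R0) or difference normalization.
#' @param b_tail baseline tail points averaged for the reference.
#' @param median_window odd median-filter width.
#' @param outlier_alpha tail probability for outlier cutoffs.
#' @param outlier_var_explained retained PCA variance fraction.
#' @param stages stage order; fixed, validated.
#' @return A named list of settings.
#' @export
preprocess_config <- function(trim = "head", normalize = "ratio",
                              b_tail = 10L, median_window = 3L,
                              outlier_alpha = 0.01,
                              outlier_var_explained = 0.95,
                              stages = c("equalize", "normalize", "filter")) {
  if (!identical(as.character(stages), c("equalize", "normalize", "filter")))
    stop("invalid stage order: must be equalize, normalize, filter")
  list(trim = trim, normalize = normalize, b_tail = as.integer(b_tail),
       median_window = as.integer(median_window),
       outlier_alpha = outlier_alpha,
       outlier_var_explained = outlier_var_explained)
}

#' Preprocess a screened cohort into per-sensor curve panels
#'
#' Per sensor: equalize lengths (keep the tail), normalize each breath curve
#' against its own baseline tail, median-filter. Outlier detection then runs
#' once on the column-concatenation of all per-sensor panels, and flagged
#' measurements are removed from every panel, keeping the panels row-aligned.
#'
#' @param cohort a screened [breath_cohort()].
#' @param config a [preprocess_config()].
#' @return List with elements `panels` (named list of [curve_panel()], one per
#'   sensor), `outliers` (the [detect_outliers()] report), and
#'   `removed` (ids of measurements dropped as outliers).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  ms <- kept_measurements(cohort)
  if (length(ms) == 0L) stop("no kept measurements to preprocess")
  ids <- vapply(ms, function(m) m$measurement_id, character(1))
  sensor_ids <- names(ms[[1L]]$sensors)

  panels <- lapply(sensor_ids, function(sid) {
    breaths <- lapply(ms, function(m) m$sensors[[sid]]$breath)
    breaths <- equalize_lengths(breaths, trim = config$trim)
    curves <- t(vapply(seq_along(ms), function(i) {
      y <- normalize_to_baseline(breaths[[i]], ms[[i]]$sensors[[sid]]$baseline,
                                 mode = config$normalize,
                                 b_tail = config$b_tail)
      median_filter(y, config$median_window)
    }, numeric(length(breaths[[1L]]))))
    curve_panel(sid, curves, ids)
  })
  names(panels) <- sensor_ids

  wide <- do.call(cbind, lapply(panels, function(p) p$curves))
  rep_out <- detect_outliers(wide, alpha = config$outlier_alpha,
                             var_explained = config$outlier_var_explained,
                             row_ids = ids)
  removed <- rep_out$measurement_id[rep_out$flagged]
  if (length(removed)) {
    keep <- !(ids %in% removed)
    panels <- lapply(panels, function(p)
      curve_panel(p$sensor_id, p$curves[keep, , drop = FALSE], ids[keep]))
    message(sprintf("preprocess_cohort: removed %d outlier measurement(s)",
                    length(removed)))
  }
  list(panels = panels, outliers = rep_out, removed = removed)
}
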