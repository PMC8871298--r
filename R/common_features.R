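## Conventional scalar curve descriptors used as the comparison feature set:
## minimum, maximum, average, trapezoidal area under the curve, and the mean
## of the stable end part of the curve.

#' Extract the common scalar features of one curve
#'
#' @param curve numeric vector of length T (a preprocessed response curve).
#' @param end_window number of final points averaged for `end_mean`
#'   (default 10); must not exceed T.
#' @return Named numeric vector: `minimum`, `maximum`, `average`, `auc`
#'   (trapezoidal integral at unit spacing), `end_mean`.
#' @export
extract_common <- function(curve, end_window = 10L) {
  T <- length(curve)
  if (end_window < 1L || end_window > T)
    stop("end_window must lie in [1, length(curve)]")
  auc <- sum((curve[-1] + curve[-T]) / 2)
  c(minimum = min(curve), maximum = max(curve), average = mean(curve),
    auc = auc, end_mean = mean(curve[(T - end_window + 1L):T]))
}

COMMON_FEATURE_NAMES <- c("minimum", "maximum", "average", "auc", "end_mean")

# Panels must be row-aligned: identical ordered measurement_id lists.
assert_aligned_panels <- function(panels) {
  ref <- panels[[1L]]$measurement_ids
  for (p in panels) {
    if (!identical(p$measurement_ids, ref))
      stop("panels are not row-aligned across sensors")
  }
  ref
}

#' Build the common-feature table for a set of panels
#'
#' One numeric column per (sensor, feature) pair: 5 columns per sensor,
#' named `<sensor>_<feature>`.
#'
#' @param panels named list of row-aligned [curve_panel()] objects.
#' @param labels named character vector of class labels (names are
#'   measurement ids); every panel row must have a label.
#' @param end_window passed to [extract_common()].
#' @return data.frame with columns `measurement_id`, `label`, then the
#'   numeric feature columns.
#' @export
common_feature_table <- function(panels, labels, end_window = 10L) {
  ids <- assert_aligned_panels(panels)
  if (!all(ids %in% names(labels)))
    stop("label missing for measurement(s): ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  cols <- lapply(panels, function(p) {
    f <- t(apply(p$curves, 1L, extract_common, end_window = end_window))
    colnames(f) <- paste(p$sensor_id, COMMON_FEATURE_NAMES, sep = "_")
    f
  })
  out <- data.frame(measurement_id = ids, label = unname(labels[ids]),
                    do.call(cbind, cols),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out
}
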