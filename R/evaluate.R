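## Repeated-holdout evaluation: per-run stratified splits with all
## training-derived artifacts (taxonomies, discretization, scores, selection,
## model) fit strictly on the training portion; metric aggregation with 95%
## t-intervals; ANOVA + Bonferroni comparison across configurations.

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with midrank tie handling: equal scores
#' contribute 1/2, so all-equal scores give 0.5. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric cancer-class scores.
#' @param labels class labels; `"cancer"` is positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == POSITIVE_CLASS
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUROC")
  r <- rank(scores) # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fn,tn,fp confusion counts with cancer as the positive class.
#' @return Named list: the counts plus `accuracy`, `sensitivity`,
#'   `specificity` as percentages.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  list(TP = tp, FN = fn, TN = tn, FP = fp,
       accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp))
}

# Stratified holdout split; returns list(train=, test=) of row indices.
split_stratified <- function(labels, test_fraction) {
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(test_fraction * length(idx)))
    if (length(idx) - n_test < 1L) n_test <- length(idx) - 1L
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

subset_panels <- function(panels, keep) {
  lapply(panels, function(p)
    curve_panel(p$sensor_id, p$curves[keep, , drop = FALSE],
                p$measurement_ids[keep]))
}

#' Pipeline configuration for one evaluation run
#'
#' @param features `"taxonomy"` (cluster-membership features) or `"common"`
#'   (scalar curve summaries).
#' @param distance,linkage,k_range,band taxonomy settings (see
#'   [shape_taxonomy()]); ignored for common features.
#' @param selector `"infogain"`, `"symm_unc"`, `"relieff"` or `"none"`.
#' @param top_m selection budget (see [select_features()]).
#' @param classifier `"nb"`, `"svm"` or `"rf"`.
#' @param test_fraction held-out fraction per run (default 0.3).
#' @param transductive if `TRUE`, taxonomies are clustered once on all rows
#'   instead of per-run training rows (leakage-prone; off by default).
#' @param end_window end-mean window for common features.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(features = c("taxonomy", "common"),
                            distance = "euclidean", linkage = "ward",
                            k_range = 2:10, band = NULL,
                            selector = c("infogain", "symm_unc", "relieff",
                                         "none"),
                            top_m = 26L,
                            classifier = c("nb", "svm", "rf"),
                            test_fraction = 0.3, transductive = FALSE,
                            end_window = 10L) {
  structure(list(features = match.arg(features),
                 distance = match.arg(distance, c("euclidean", "dtwarp")),
                 linkage = match.arg(linkage, c("complete", "ward")),
                 k_range = k_range, band = band,
                 selector = match.arg(selector),
                 top_m = top_m, classifier = match.arg(classifier),
                 test_fraction = test_fraction,
                 transductive = isTRUE(transductive),
                 end_window = end_window),
            class = "pipeline_config")
}

config_id <- function(cfg) {
  if (cfg$features == "common")
    paste("common", cfg$selector, cfg$classifier, sep = "_")
  else
    paste("taxonomy", cfg$distance, cfg$linkage, cfg$selector, cfg$classifier,
          sep = "_")
}

#' One feature selection / training / testing cycle
#'
#' Draws a stratified holdout split, builds the configured feature table with
#' every training-derived artifact (taxonomy, discretization, scores,
#' selection, classifier) fit on the training rows only, and evaluates on the
#' held-out rows. If a drawn test fold misses a class the split is redrawn
#' with the next seed (at most 10 attempts).
#'
#' @param panels named list of row-aligned [curve_panel()] objects.
#' @param labels named character vector of class labels.
#' @param config a [pipeline_config()].
#' @param seed integer seed for the split (and the Random Forest).
#' @return List of class `run_result`: `seed`, `confusion`, `accuracy`,
#'   `sensitivity`, `specificity` (percent), `auroc`, `selected`, `n_test`.
#' @export
evaluate_run <- function(panels, labels, config, seed) {
  ids <- assert_aligned_panels(panels)
  y <- unname(labels[ids])
  assert_training_labels(y)

  split <- NULL
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    cand <- split_stratified(y, config$test_fraction)
    if (length(unique(y[cand$test])) >= 2L &&
        length(unique(y[cand$train])) >= 2L) { split <- cand; break }
  }
  if (is.null(split)) stop("could not draw a split containing both classes")

  if (config$features == "taxonomy") {
    tax_panels <- if (config$transductive) panels
                  else subset_panels(panels, split$train)
    taxonomies <- build_taxonomies(tax_panels, distance = config$distance,
                                   linkage = config$linkage,
                                   k_range = config$k_range,
                                   band = config$band)
    table <- membership_feature_table(taxonomies, panels, labels)
  } else {
    table <- common_feature_table(panels, labels,
                                  end_window = config$end_window)
  }
  train_tab <- table[split$train, , drop = FALSE]
  test_tab <- table[split$test, , drop = FALSE]

  if (config$selector != "none") {
    scores <- score_features(train_tab, method = config$selector)
    selected <- select_features(scores, policy = "top_m", m = config$top_m)
    keep <- c("measurement_id", "label", selected)
    train_tab <- train_tab[, keep, drop = FALSE]
    test_tab <- test_tab[, keep, drop = FALSE]
  } else {
    selected <- setdiff(names(table), c("measurement_id", "label"))
  }

  model <- train_classifier(train_tab, algorithm = config$classifier,
                            seed = seed)
  sc <- predict_scores(model, test_tab)
  pred <- ifelse(sc >= 0.5, POSITIVE_CLASS, "control")
  truth <- test_tab$label
  cm <- confusion_metrics(
    tp = sum(pred == POSITIVE_CLASS & truth == POSITIVE_CLASS),
    fn = sum(pred != POSITIVE_CLASS & truth == POSITIVE_CLASS),
    tn = sum(pred != POSITIVE_CLASS & truth != POSITIVE_CLASS),
    fp = sum(pred == POSITIVE_CLASS & truth != POSITIVE_CLASS))

  structure(list(seed = seed,
                 confusion = cm[c("TP", "FN", "TN", "FP")],
                 accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                 specificity = cm$specificity,
                 auroc = auroc(sc, truth),
                 selected = selected, n_test = length(split$test)),
            class = "run_result")
}

EVAL_METRICS <- c("accuracy", "sensitivity", "specificity", "auroc")

#' Aggregate repeated-run metrics
#'
#' Mean and 95% t-interval (`mean +/- t_{0.975, n-1} s / sqrt(n)`) per
#' metric.
#'
#' @param results list of at least 2 [evaluate_run()] results from the same
#'   configuration.
#' @param configuration optional configuration id to record.
#' @return data.frame with one row per metric: `metric`, `mean`, `ci_low`,
#'   `ci_high`, `n_runs`.
#' @export
aggregate_runs <- function(results, configuration = NA_character_) {
  n <- length(results)
  if (n < 2L) stop("need at least 2 runs to aggregate")
  rows <- lapply(EVAL_METRICS, function(mt) {
    v <- vapply(results, function(r) r[[mt]], numeric(1))
    m <- mean(v)
    half <- qt(0.975, n - 1L) * sd(v) / sqrt(n)
    data.frame(configuration = configuration, metric = mt, mean = m,
               ci_low = m - half, ci_high = m + half, n_runs = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare configurations by ANOVA with Bonferroni post-hoc tests
#'
#' @param metric_by_config named list (>= 2 entries) of per-run metric
#'   vectors, one entry per configuration.
#' @return List with `anova_p` (one-way ANOVA p-value) and `pairwise`
#'   (data.frame of pairwise two-sample t-tests with p-values multiplied by
#'   the number of pairs, capped at 1).
#' @export
compare_configurations <- function(metric_by_config) {
  if (length(metric_by_config) < 2L) stop("need at least 2 configurations")
  if (any(lengths(metric_by_config) == 0L)) stop("empty configuration group")
  gvals <- unlist(metric_by_config, use.names = FALSE)
  gnames <- factor(rep(names(metric_by_config), lengths(metric_by_config)))
  fit <- aov(gvals ~ gnames)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]

  nms <- names(metric_by_config)
  pairs <- utils::combn(nms, 2L)
  npairs <- ncol(pairs)
  pw <- data.frame(config_a = pairs[1L, ], config_b = pairs[2L, ],
                   p_adj = NA_real_, stringsAsFactors = FALSE)
  for (q in seq_len(npairs)) {
    a <- metric_by_config[[pairs[1L, q]]]
    b <- metric_by_config[[pairs[2L, q]]]
    p <- if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) 1
         else t.test(a, b)$p.value
    pw$p_adj[q] <- min(1, p * npairs)
  }
  list(anova_p = anova_p, pairwise = pw)
}

#' Run the full factorial experiment matrix
#'
#' Executes `n_runs` evaluation cycles for every configuration, using one set
#' of per-run seeds spawned from the master seed (splits are therefore paired
#' across configurations), and aggregates each configuration's metrics.
#'
#' @param panels named list of row-aligned [curve_panel()] objects.
#' @param labels named character vector of class labels.
#' @param configs list of [pipeline_config()] objects (named or not;
#'   unnamed configs are labelled by their settings).
#' @param n_runs evaluation cycles per configuration (>= 2).
#' @param master_seed integer master seed.
#' @return Object of class `breath_eval`: a data.frame of aggregated metrics
#'   (one block of rows per configuration), with the per-run results stored
#'   in `attr(, "per_run")`.
#' @export
run_experiment_matrix <- function(panels, labels, configs, n_runs = 1000L,
                                  master_seed = 1L) {
  if (n_runs < 2L) stop("n_runs must be at least 2 (aggregation needs >= 2)")
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    names(configs) <- vapply(configs, config_id, character(1))
  set.seed(master_seed)
  run_seeds <- sample.int(.Machine$integer.max - 10L, n_runs)

  per_run <- lapply(configs, function(cfg)
    lapply(run_seeds, function(s) evaluate_run(panels, labels, cfg, seed = s)))
  agg <- do.call(rbind, lapply(names(configs), function(nm)
    aggregate_runs(per_run[[nm]], configuration = nm)))
  rownames(agg) <- NULL
  structure(agg, per_run = per_run, master_seed = master_seed,
            class = c("breath_eval", "data.frame"))
}

#' Per-run metric vectors of an experiment matrix
#'
#' @param eval_result a [run_experiment_matrix()] result.
#' @param metric one of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"auroc"`.
#' @return Named list of numeric per-run vectors, one per configuration
#'   (ready for [compare_configurations()]).
#' @export
per_run_metric <- function(eval_result, metric = EVAL_METRICS) {
  metric <- match.arg(metric)
  lapply(attr(eval_result, "per_run"), function(runs)
    vapply(runs, function(r) r[[metric]], numeric(1)))
}

#' @export
print.breath_eval <- function(x, digits = 2, ...) {
  cat("breath_eval: repeated-holdout evaluation\n")
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
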