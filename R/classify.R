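## Classifier training and scoring. The cancer class is the positive class
## throughout. Naive Bayes treats nominal membership columns as categorical
## (Laplace add-1) and numeric columns as per-class Gaussians; the linear SVM
## one-hot encodes nominal columns and calibrates probabilities by logistic
## regression on its training decision values; the Random Forest uses 100
## trees with sqrt-feature subsampling under the supplied seed.

POSITIVE_CLASS <- "cancer"

one_hot <- function(feats, schema = NULL) {
  cols <- list()
  for (nm in names(feats)) {
    col <- feats[[nm]]
    if (is.numeric(col)) {
      cols[[nm]] <- col
    } else {
      levs <- if (!is.null(schema)) schema[[nm]] else levels(factor(col))
      for (lv in levs)
        cols[[paste0(nm, "=", lv)]] <- as.numeric(as.character(col) == lv)
    }
  }
  do.call(cbind, cols)
}

feature_frame <- function(table) {
  table[, setdiff(names(table), c("measurement_id", "label")), drop = FALSE]
}

#' Train a classifier on a feature table
#'
#' @param table feature data.frame (`measurement_id`, `label`, features);
#'   the label column must contain at least 2 classes, each with >= 2 rows.
#' @param algorithm `"nb"`, `"svm"` or `"rf"`.
#' @param seed integer seed (used by the Random Forest; the other two are
#'   deterministic).
#' @return Object of class `breath_classifier` recording the algorithm, the
#'   fit, and the input schema (feature names and factor levels) used to
#'   validate prediction inputs.
#' @export
train_classifier <- function(table, algorithm = c("nb", "svm", "rf"),
                             seed = 1L) {
  algorithm <- match.arg(algorithm)
  assert_training_labels(table$label)
  y <- factor(table$label)
  feats <- feature_frame(table)
  if (ncol(feats) == 0L) stop("no feature columns")
  schema <- lapply(feats, function(col)
    if (is.numeric(col)) "numeric" else levels(factor(col)))

  if (algorithm == "nb") {
    fit <- e1071::naiveBayes(x = feats, y = y, laplace = 1)
    calib <- NULL
  } else if (algorithm == "svm") {
    X <- one_hot(feats, schema)
    keep <- apply(X, 2L, function(v) var(v) > 0)
    if (!any(keep)) stop("all features constant")
    X <- X[, keep, drop = FALSE]
    fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = 1,
                      scale = FALSE)
    dv <- drop(attr(predict(fit, X, decision.values = TRUE),
                    "decision.values"))
    y01 <- as.numeric(y == POSITIVE_CLASS)
    calib <- suppressWarnings(glm(y01 ~ dv, family = binomial()))
    attr(fit, "kept_columns") <- colnames(X)
  } else {
    set.seed(seed)
    fit <- randomForest::randomForest(x = feats, y = y, ntree = 100L)
    calib <- NULL
  }
  structure(list(algorithm = algorithm, fit = fit, calibration = calib,
                 schema = schema, classes = levels(y), seed = seed),
            class = "breath_classifier")
}

#' Positive-class (cancer) scores for new rows
#'
#' @param model a [train_classifier()] result.
#' @param table feature data.frame with the same feature columns the model
#'   was trained on.
#' @return Numeric vector of cancer-class scores in `[0, 1]`.
#' @export
predict_scores <- function(model, table) {
  feats <- feature_frame(table)
  missing_cols <- setdiff(names(model$schema), names(feats))
  if (length(missing_cols))
    stop("prediction input missing feature(s): ",
         paste(missing_cols, collapse = ", "))
  feats <- feats[, names(model$schema), drop = FALSE]
  for (nm in names(feats)) {
    if (!identical(model$schema[[nm]], "numeric"))
      feats[[nm]] <- factor(as.character(feats[[nm]]),
                            levels = model$schema[[nm]])
  }
  if (model$algorithm == "nb") {
    pr <- predict(model$fit, feats, type = "raw")
    unname(pr[, POSITIVE_CLASS])
  } else if (model$algorithm == "svm") {
    X <- one_hot(feats, model$schema)
    X <- X[, attr(model$fit, "kept_columns"), drop = FALSE]
    dv <- drop(attr(predict(model$fit, X, decision.values = TRUE),
                    "decision.values"))
    unname(predict(model$calibration, data.frame(dv = dv),
                   type = "response"))
  } else {
    pr <- predict(model$fit, feats, type = "prob")
    unname(pr[, POSITIVE_CLASS])
  }
}

#' @export
print.breath_classifier <- function(x, ...) {
  cat(sprintf("breath_classifier: %s on %d features (classes: %s)\n",
              toupper(x$algorithm), length(x$schema),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
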