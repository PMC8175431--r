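# Tree-family benchmark models and the bootstrapped null-performance
# threshold. Two variants per family: plain models fit on the original
# training rows, and "robust" models fit on the masked-augmented,
# median-imputed training set (imputation always uses training-split
# medians, never test statistics).

#' Baseline model specification
#'
#' @param family `"decision_tree"` (CART via rpart, unconstrained depth) or
#'   `"random_forest"` (ranger, impurity importance)
#' @param robust whether the model is to be trained on masked-augmented,
#'   median-imputed data
#' @param n_trees forest size for the random forest
#' @param max_depth tree depth cap (30 = rpart's maximum, i.e. effectively
#'   unlimited at this feature scale)
#' @param seed seed for the forest's bootstrap resampling
#' @return a `baseline_spec` list
#' @export
baseline_spec <- function(family = c("decision_tree", "random_forest"),
                          robust = FALSE, n_trees = 100L, max_depth = 30L,
                          seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, robust = robust,
                 n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Fit a tree-family baseline
#'
#' The caller supplies the appropriate training table: the original complete
#' split for plain models, or the augmented + imputed split for robust ones.
#' The fitted model carries impurity-based per-item feature importances
#' normalized to sum to 1 (items the model never split on get 0).
#'
#' @param spec a [baseline_spec()]
#' @param train training dataset (item columns + `label`, no missing values)
#' @return a `baseline_model` with elements `fit`, `spec`, `importance`
#' @export
fit_baseline <- function(spec, train) {
  items <- setdiff(names(train), "label")
  if (length(unique(train$label)) < 2L)
    stop("baseline training data must contain both classes")
  if (anyNA(train[items]))
    stop("baseline training data must be complete (impute first)")
  form <- stats::as.formula(paste("label ~", paste(items, collapse = " + ")))
  if (spec$family == "decision_tree") {
    fit <- rpart::rpart(form, data = train, method = "class",
                        control = rpart::rpart.control(
                          cp = 0, minsplit = 2, minbucket = 1,
                          maxdepth = spec$max_depth, xval = 0,
                          maxsurrogate = 0, maxcompete = 0))
    raw <- fit$variable.importance
    imp <- stats::setNames(numeric(length(items)), items)
    if (!is.null(raw)) imp[names(raw)] <- raw
  } else {
    set.seed(spec$seed)
    fit <- ranger::ranger(form, data = train, num.trees = spec$n_trees,
                          importance = "impurity", num.threads = 1L,
                          verbose = FALSE, seed = spec$seed)
    imp <- fit$variable.importance[items]
  }
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) == 0) stats::setNames(rep(1 / length(items), length(items)), items)
         else imp / sum(imp)
  structure(list(fit = fit, spec = spec, importance = imp, items = items),
            class = "baseline_model")
}

#' Predict labels with a fitted baseline
#'
#' @param object a `baseline_model`
#' @param newdata complete data.frame of item scores (impute masked entries
#'   with the training medians first)
#' @param ... unused
#' @return factor of predicted labels
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  if (object$spec$family == "decision_tree") {
    p <- predict(object$fit, newdata = newdata, type = "class")
  } else {
    p <- predict(object$fit, data = newdata, num.threads = 1L)$predictions
  }
  p
}

#' Bootstrapped null F1 threshold
#'
#' How well does label-guessing do? For a stratified held-out fold, each
#' trial draws every predicted label independently from the empirical class
#' distribution and scores minority-class F1 against the fold's true labels;
#' the requested percentile of the trial distribution is the bar a model
#' must clear to beat chance.
#'
#' @param class_counts named or unnamed 2-vector of per-class sample counts
#'   (majority first if unnamed)
#' @param fold_size held-out fold size (stratified from `class_counts`)
#' @param n_trials number of bootstrap trials
#' @param percentile percentile of the F1 distribution to return, in (0,100)
#' @return list with `threshold`, the F1 `distribution`, and the fold
#'   composition used
#' @export
bootstrap_null <- function(class_counts, fold_size = 46L, n_trials = 10000L,
                           percentile = 95) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (percentile <= 0 || percentile >= 100) stop("percentile must lie in (0,100)")
  counts <- sort(as.numeric(class_counts), decreasing = TRUE)
  total <- sum(counts)
  p_min <- counts[2] / total
  n_min <- round(fold_size * p_min)
  n_maj <- fold_size - n_min
  if (n_min < 1L || n_maj < 1L)
    stop("degenerate fold: stratification leaves a class empty")
  # truth: n_min minority, n_maj majority; predictions iid Bernoulli(p_min)
  draws <- matrix(stats::runif(n_trials * fold_size) < p_min, n_trials, fold_size)
  tp <- rowSums(draws[, seq_len(n_min), drop = FALSE])
  fp <- rowSums(draws[, n_min + seq_len(n_maj), drop = FALSE])
  fn <- n_min - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, 2 * tp / denom)
  list(threshold = unname(stats::quantile(f1, percentile / 100)),
       distribution = f1,
       fold = c(minority = n_min, majority = n_maj),
       n_trials = n_trials, percentile = percentile)
}
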