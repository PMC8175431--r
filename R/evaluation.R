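# Cross-validated robustness evaluation: stratified k-fold plans,
# minority-class F1, combinatorial masking of held-out folds, and
# feature-importance dispersion summaries.

#' Stratified k-fold cross-validation plan
#'
#' Shuffles each class separately and deals samples round-robin, so every
#' fold's class ratio is within one sample of the global ratio.
#'
#' @param data dataset with a `label` column
#' @param k number of folds
#' @param seed integer seed
#' @return a `cv_plan`: list with `fold` (per-sample fold index), `k`, `seed`
#' @export
make_cv_plan <- function(data, k = 10L, seed = 1L) {
  lab <- data$label
  if (any(table(lab) < k))
    stop("every class must have at least k samples")
  set.seed(seed)
  fold <- integer(nrow(data))
  for (cl in unique(lab)) {
    idx <- sample(which(lab == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_plan")
}

# least frequent class label
minority_class <- function(labels) {
  tab <- table(labels)
  names(sort(tab, decreasing = FALSE))[1]
}

#' Binary F1 score
#'
#' `2 TP / (2 TP + FP + FN)`, with the convention that an empty denominator
#' (no true and no predicted positives) scores 0.
#'
#' @param preds predicted labels
#' @param truth true labels (same length)
#' @param positive the class treated as positive (package convention: the
#'   minority, ADHD-like class)
#' @return numeric scalar in \[0,1\]
#' @export
f1 <- function(preds, truth, positive) {
  if (length(preds) != length(truth)) stop("preds and truth differ in length")
  p <- preds == positive
  t <- truth == positive
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  denom <- 2 * tp + fp + fn
  if (denom == 0) 0 else 2 * tp / denom
}

#' Fit all per-fold models
#'
#' For one training split: training medians, the masked-augmented set, the
#' belief model G, the Q-learning policy (trained on the complete split),
#' and the four tree baselines (plain on the complete split, robust on the
#' augmented + median-imputed one).
#'
#' @param train complete training split
#' @param scheme [augmentation_scheme()] for G and the robust baselines
#' @param params [reward_params()]
#' @param cfg [train_config()]
#' @param n_trees forest size
#' @param seed seed for the tree learners
#' @param smoothing belief-model pseudo-count
#' @return list of fitted models plus `medians`
#' @export
fit_fold_models <- function(train, scheme = augmentation_scheme(),
                            params = NULL, cfg = train_config(),
                            n_trees = 100L, seed = 1L, smoothing = 1) {
  medians <- training_medians(train)
  aug <- augment_training(train, scheme)
  g <- fit_belief(aug, smoothing = smoothing)
  policy <- train_policy(train, g, params = params, cfg = cfg)
  aug_imp <- impute_median(aug, medians)
  models <- list(
    DT = fit_baseline(baseline_spec("decision_tree", seed = seed), train),
    RF = fit_baseline(baseline_spec("random_forest", n_trees = n_trees,
                                    seed = seed), train),
    DT_robust = fit_baseline(baseline_spec("decision_tree", robust = TRUE,
                                           seed = seed), aug_imp),
    RF_robust = fit_baseline(baseline_spec("random_forest", robust = TRUE,
                                           n_trees = n_trees, seed = seed),
                             aug_imp))
  c(models, list(policy = policy, belief = g, medians = medians))
}

#' Combinatorial-masking robustness evaluation
#'
#' For every fold and every mask size n, applies each of the `choose(m, n)`
#' masks to every held-out row. Tree-family models receive the masked
#' entries median-imputed from their fold's training split; the policy
#' receives them encoded as 0 (missing). F1 is computed over the pooled
#' masked copies within each (fold, mask size) and then averaged across
#' folds — pooling stabilizes the minority-class F1 on small folds.
#'
#' @param fold_models list (one element per fold) as returned by
#'   [fit_fold_models()]
#' @param plan the [make_cv_plan()] used to create the folds
#' @param data the full dataset
#' @param mask_sizes mask sizes to evaluate; default `0:(m-1)` (the fully
#'   masked case is degenerate for every model and excluded from headline
#'   metrics)
#' @return list with `report` (mean F1 and mean questions per model and
#'   mask size), `by_fold` (the unaggregated grid)
#' @export
robustness_eval <- function(fold_models, plan, data, mask_sizes = NULL) {
  items <- setdiff(names(data), "label")
  m <- length(items)
  if (is.null(mask_sizes)) mask_sizes <- 0:(m - 1)
  minority <- minority_class(data$label)
  tree_names <- c("DT", "RF", "DT_robust", "RF_robust")
  out <- list()

  for (f in seq_along(fold_models)) {
    fm <- fold_models[[f]]
    test <- data[plan$fold == f, , drop = FALSE]
    scores <- as.matrix(test[items])
    nr <- nrow(scores)
    for (n in mask_sizes) {
      masks <- enumerate_masks(m, n)
      K <- length(masks)
      big <- scores[rep(seq_len(nr), times = K), , drop = FALSE]
      for (k in seq_along(masks)) {
        if (length(masks[[k]]))
          big[((k - 1) * nr + 1):(k * nr), masks[[k]]] <- NA
      }
      truth <- rep(test$label, times = K)

      pol <- evaluate_policy(fm$policy, big)
      out[[length(out) + 1L]] <- data.frame(
        fold = f, mask_size = n, model = "policy",
        f1 = f1(pol$pred, truth, minority),
        mean_questions = mean(pol$questions))

      imp_df <- impute_median(as.data.frame(big), fm$medians)
      for (mn in tree_names) {
        preds <- predict(fm[[mn]], imp_df)
        out[[length(out) + 1L]] <- data.frame(
          fold = f, mask_size = n, model = mn,
          f1 = f1(preds, truth, minority), mean_questions = NA_real_)
      }
    }
  }
  by_fold <- do.call(rbind, out)
  report <- stats::aggregate(cbind(f1, mean_questions) ~ model + mask_size,
                             data = by_fold, FUN = mean, na.action = NULL)
  report <- report[order(report$model, report$mask_size), ]
  rownames(report) <- NULL
  list(report = report, by_fold = by_fold)
}

#' Feature-importance dispersion report
#'
#' Population variance and range of each model's importance vector —
#' low dispersion means the model spreads its attention evenly over items.
#'
#' @param importances named list of importance vectors, each summing to 1
#' @return data.frame with columns `model`, `variance`, `range`
#' @export
importance_report <- function(importances) {
  stopifnot(length(importances) > 0)
  rows <- lapply(names(importances), function(nm) {
    v <- importances[[nm]]
    data.frame(model = nm,
               variance = mean((v - mean(v))^2),
               range = max(v) - min(v))
  })
  do.call(rbind, rows)
}

#' Run the full cross-validated experiment
#'
#' Generates nothing itself: takes a complete dataset, builds a stratified
#' CV plan, fits per-fold belief models, policies and tree baselines, then
#' evaluates all of them under combinatorial masking and summarizes feature
#' importances (averaged across folds per model).
#'
#' @param data complete dataset (item columns + `label`)
#' @param k folds
#' @param seed global seed (fold plan, dev splits, tree learners)
#' @param scheme [augmentation_scheme()]
#' @param params [reward_params()]
#' @param cfg [train_config()]
#' @param n_trees forest size
#' @param mask_sizes mask sizes to evaluate (default `0:(m-1)`)
#' @param keep_models keep per-fold fitted models in the result
#' @return list with `report`, `by_fold`, `importance` (per-model averaged
#'   vectors), `importance_report`, `plan`, optionally `fold_models`
#' @export
run_experiment <- function(data, k = 10L, seed = 1L,
                           scheme = augmentation_scheme(),
                           params = NULL, cfg = train_config(),
                           n_trees = 100L, mask_sizes = NULL,
                           keep_models = FALSE) {
  plan <- make_cv_plan(data, k = k, seed = seed)
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    set.seed(seed * 1000L + f)
    fold_models[[f]] <- fit_fold_models(data[plan$fold != f, , drop = FALSE],
                                        scheme = scheme, params = params,
                                        cfg = cfg, n_trees = n_trees,
                                        seed = seed + f)
  }
  ev <- robustness_eval(fold_models, plan, data, mask_sizes = mask_sizes)

  model_names <- c("DT", "RF", "DT_robust", "RF_robust", "policy")
  importance <- lapply(stats::setNames(model_names, model_names), function(mn) {
    vecs <- lapply(fold_models, function(fm) {
      if (mn == "policy") policy_feature_importance(fm$policy)$importance
      else fm[[mn]]$importance
    })
    Reduce(`+`, vecs) / length(vecs)
  })
  res <- list(report = ev$report, by_fold = ev$by_fold,
              importance = importance,
              importance_report = importance_report(importance),
              plan = plan, seed = seed)
  if (keep_models) res$fold_models <- fold_models
  res
}

#' Plot F1 degradation curves
#'
#' Mean F1 against the number of masked items, one line per model; the
#' optional horizontal line marks a bootstrapped null threshold.
#'
#' @param report the `report` data.frame from [robustness_eval()]
#' @param null_threshold optional numeric
#' @export
plot_degradation <- function(report, null_threshold = NULL) {
  models <- unique(report$model)
  sizes <- sort(unique(report$mask_size))
  cols <- seq_along(models)
  graphics::plot(NULL, xlim = range(sizes), ylim = c(0, 1),
                 xlab = "items masked", ylab = "F1 (minority class)",
                 main = "F1 degradation under feature masking")
  for (i in seq_along(models)) {
    sub <- report[report$model == models[i], ]
    graphics::lines(sub$mask_size, sub$f1, col = cols[i], lwd = 2)
    graphics::points(sub$mask_size, sub$f1, col = cols[i], pch = 16)
  }
  if (!is.null(null_threshold))
    graphics::abline(h = null_threshold, lty = 2, col = "grey40")
  graphics::legend("topright", legend = models, col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot per-item feature importances
#'
#' @param importance named list of per-model importance vectors
#' @export
plot_importance <- function(importance) {
  mat <- do.call(rbind, importance)
  graphics::barplot(mat, beside = TRUE, legend.text = rownames(mat),
                    las = 2, ylab = "normalized importance",
                    main = "Feature importance by model")
  invisible(NULL)
}
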