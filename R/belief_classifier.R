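# The belief classifier G: a categorical Naive Bayes model over observation
# codes that maps any partial observation to a 2-class posterior ("belief").
# Missingness is a first-class category — code 0 has its own likelihood —
# so G consumes partially observed states directly, with no imputation.
# Trained on the masked-augmented training split, G supplies the policy's
# intermediate rewards and its final prediction.

#' Fit the Naive Bayes belief model
#'
#' Observations are coded per item as 0 (missing) or raw score + 1, and code
#' 0 is treated as an ordinary category in the per-item likelihoods: fitting
#' on a masked training set teaches G how much (or little) missingness says
#' about each class. Priors and likelihoods are additive-smoothed
#' (pseudo-count `smoothing` per cell) so no code ever has probability zero.
#'
#' Class priors default to uniform: the model's job is to keep the minority
#' diagnosis detectable from sparse observations, and an imbalanced prior
#' (odds near 3:1 in the emulated cohort) would swamp the evidence any
#' single ordinal item can carry, collapsing sparse-state predictions onto
#' the majority class. Empirical (smoothed class-frequency) priors are
#' available via `prior = "empirical"`.
#'
#' @param data dataset with item columns (raw scores, `NA` = missing) and a
#'   `label` column with exactly two classes
#' @param smoothing additive pseudo-count, > 0
#' @param prior `"uniform"` (default) or `"empirical"` (smoothed class
#'   frequencies)
#' @return a `belief_model`: classes (majority first), log-priors, and a
#'   `m x 4 x 2` array of per-item, per-code, per-class log-likelihoods
#' @export
fit_belief <- function(data, smoothing = 1, prior = c("uniform", "empirical")) {
  prior <- match.arg(prior)
  if (smoothing <= 0) stop("smoothing must be > 0")
  items <- setdiff(names(data), "label")
  lab <- as.character(data$label)
  tab <- sort(table(lab), decreasing = TRUE)
  if (length(tab) != 2L)
    stop("belief model requires exactly two classes in the training data")
  classes <- names(tab)           # majority class first; ties broken by name
  m <- length(items)
  n_c <- as.numeric(tab)
  priors <- if (prior == "uniform") c(0.5, 0.5)
            else (n_c + smoothing) / (sum(n_c) + 2 * smoothing)
  loglik <- array(NA_real_, c(m, 4L, 2L),
                  dimnames = list(items, paste0("code", 0:3), classes))
  for (ci in 1:2) {
    sub <- data[lab == classes[ci], items, drop = FALSE]
    for (i in seq_len(m)) {
      codes <- scores_to_codes(sub[[i]])
      counts <- tabulate(codes + 1L, nbins = 4L)
      loglik[i, , ci] <- log((counts + smoothing) / (n_c[ci] + 4 * smoothing))
    }
  }
  structure(list(classes = classes, log_prior = log(priors),
                 log_lik = loglik, smoothing = smoothing, prior = prior,
                 items = items),
            class = "belief_model")
}

#' @export
print.belief_model <- function(x, ...) {
  cat("Naive Bayes belief model:", length(x$items), "items; classes",
      paste(x$classes, collapse = " / "),
      sprintf("(priors %.3f / %.3f)\n", exp(x$log_prior)[1], exp(x$log_prior)[2]))
  invisible(x)
}

#' Belief (2-class posterior) of a partial observation
#'
#' The posterior is proportional to prior times the product of per-item code
#' likelihoods over all items — unobserved items contribute their code-0
#' likelihood — then normalized to sum to 1.
#'
#' @param model a [fit_belief()] model
#' @param codes observation vector (codes in \{0,1,2,3\})
#' @return named numeric 2-vector of class probabilities, majority class
#'   first
#' @export
belief <- function(model, codes) {
  codes <- .check_codes(codes)
  m <- dim(model$log_lik)[1]
  if (length(codes) != m) stop("observation length does not match the model")
  lp <- model$log_prior
  for (ci in 1:2)
    lp[ci] <- lp[ci] + sum(model$log_lik[cbind(seq_len(m), codes + 1L, ci)])
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  names(p) <- model$classes
  p
}

#' Predicted label of a partial observation
#'
#' Argmax of the belief; an exact tie goes to the majority class (the first
#' class of the model).
#'
#' @inheritParams belief
#' @return the predicted class label (character scalar)
#' @export
predict_label <- function(model, codes) {
  b <- belief(model, codes)
  model$classes[which.max(b)]   # which.max takes the first (= majority) on ties
}
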