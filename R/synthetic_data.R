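# Synthetic two-class ordinal item-score data.
#
# The clinical sample this generator emulates is a referral cohort of 463
# verbal school-aged children (344 with best clinical estimates of ASD, 119
# with ADHD) scored on caregiver-interview items rated 0 (typical) to 2
# (significantly atypical). That sample is not publicly deposited, so the
# generator reproduces its statistical skeleton: two classes with
# configurable prevalence and per-item ordinal score distributions whose
# class separation is controlled by an effect-size parameter delta per item.

# Student t statistics of the ten retained interview items, strongest first.
.screened_item_t <- c(9.2263, 7.1570, 6.5214, 6.3941, 6.3521,
                      6.2030, 6.1215, 5.7257, 4.9405, 4.7258)

# Class-conditional score model: the minority (ADHD-like) class draws from a
# fixed base categorical concentrated on scores 0-1; the majority (ASD-like)
# class mixes the base with a severity kernel concentrated on 1-2, with
# mixing weight delta_i. delta = 0 gives identical classes; delta = 1 gives
# the pure severity kernel.
.base_probs   <- c(0.60, 0.30, 0.10)
.severe_probs <- c(0.05, 0.25, 0.70)

#' Configuration for the synthetic data generator
#'
#' Defaults mirror the emulated clinical cohort: 463 samples with majority
#' prevalence 344/463, and ten items whose separations `delta` are the
#' screened items' t statistics divided by 15 — the scaling that, under the
#' generator's categorical family, makes the expected two-sample t statistic
#' at n = 463 match the clinical spread (roughly 9.2 down to 4.7).
#'
#' @param n_samples number of rows to generate (>= 2)
#' @param prevalence probability of the majority (ASD-like) class, in (0,1)
#' @param n_items number of items
#' @param item_separations per-item effect sizes delta in \[0,1\]; recycled or
#'   defaulted from the ten-item clinical spread
#' @param seed integer seed; the dataset is fully reproducible from it
#' @return a `generator_config` list
#' @export
generator_config <- function(n_samples = 463L,
                             prevalence = 344 / 463,
                             n_items = 10L,
                             item_separations = NULL,
                             seed = 1L) {
  if (n_samples < 2L) stop("n_samples must be at least 2")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie strictly in (0,1)")
  if (n_items < 1L) stop("n_items must be >= 1")
  if (is.null(item_separations)) {
    item_separations <- if (n_items == 10L) .screened_item_t / 15 else
      seq(0.62, 0.30, length.out = n_items)
  }
  if (length(item_separations) != n_items)
    stop("item_separations must have length n_items")
  if (any(item_separations < 0) || any(item_separations > 1))
    stop("item_separations must lie in [0,1]")
  structure(list(n_samples = as.integer(n_samples), prevalence = prevalence,
                 n_items = as.integer(n_items),
                 item_separations = as.numeric(item_separations),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# per-class score probabilities for one item
.item_probs <- function(delta) {
  list(minority = .base_probs,
       majority = (1 - delta) * .base_probs + delta * .severe_probs)
}

#' Generate a synthetic two-class ordinal dataset
#'
#' Labels are drawn i.i.d. with the configured majority prevalence
#' ("ASD" = majority, "ADHD" = minority); item scores are drawn from the
#' class-conditional categorical model described in the package vignette.
#'
#' @param config a [generator_config()]
#' @return a data.frame with one integer score column per item (values
#'   0/1/2) and a final `label` factor with levels `c("ASD", "ADHD")`
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_items
  is_majority <- stats::runif(n) < config$prevalence
  if (all(is_majority) || !any(is_majority))
    stop("degenerate dataset: a class is empty; adjust n_samples/prevalence/seed")
  catalog <- default_catalog(m)
  scores <- matrix(0L, n, m, dimnames = list(NULL, catalog$items))
  for (i in seq_len(m)) {
    pr <- .item_probs(config$item_separations[i])
    scores[is_majority,  i] <- sample(0:2, sum(is_majority),  TRUE, pr$majority)
    scores[!is_majority, i] <- sample(0:2, sum(!is_majority), TRUE, pr$minority)
  }
  out <- as.data.frame(scores)
  out$label <- factor(ifelse(is_majority, "ASD", "ADHD"), levels = c("ASD", "ADHD"))
  out
}

#' Rank items by two-sample Student t statistic
#'
#' Screens items by their capacity to separate the two classes: for each
#' item a pooled-variance (Student) two-sample t-test compares scores
#' between classes; items are returned sorted by decreasing |t|. The signed
#' t is majority-minus-minority, so strongly ASD-elevated items carry
#' positive t. Items with zero variance in both classes and equal means have
#' an undefined t; these are reported as 0 with a warning.
#'
#' @param data dataset as returned by [generate_dataset()] (item columns
#'   plus a `label` column)
#' @return data.frame with columns `item`, `t`, `p`, sorted by decreasing |t|
#' @export
rank_items_by_t <- function(data) {
  items <- setdiff(names(data), "label")
  lab <- data$label
  if (length(unique(lab)) != 2L) stop("both classes must be present")
  majority <- names(sort(table(lab), decreasing = TRUE))[1]
  res <- lapply(items, function(it) {
    x <- data[[it]][lab == majority]
    y <- data[[it]][lab != majority]
    if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
      warning("t undefined for item ", it, " (no variance, equal means); reported as 0")
      return(data.frame(item = it, t = 0, p = 1))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(item = it, t = unname(tt$statistic), p = tt$p.value)
  })
  res <- do.call(rbind, res)
  res[order(-abs(res$t)), , drop = FALSE]
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level, in (0,1)
#' @param n_tests number of tests performed (>= 1)
#' @return the per-test threshold `alpha / n_tests`
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (n_tests < 1L) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Write a dataset as delimited text
#'
#' One row per child, one column per item, final column `label`; missing
#' scores are written as empty fields.
#'
#' @param data dataset (item columns + `label`)
#' @param path output CSV path
#' @export
write_dataset <- function(data, path) {
  utils::write.table(data, path, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path CSV path
#' @return data.frame with integer item columns (NA = missing) and a
#'   `label` factor, majority class as the first level
#' @export
read_dataset <- function(path) {
  data <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (!"label" %in% names(data)) stop("dataset must contain a 'label' column")
  items <- setdiff(names(data), "label")
  for (it in items) data[[it]] <- as.integer(data[[it]])
  lev <- names(sort(table(data$label), decreasing = TRUE))
  data$label <- factor(data$label, levels = lev)
  data
}
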