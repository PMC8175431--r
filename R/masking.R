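# Feature masking: the robustness probe. A "corrupted" copy of a sample is
# produced by hiding a subset of its item scores; tree models receive the
# hidden entries median-imputed from the training split, while the policy
# sees them as code 0 (missing).

#' Enumerate all masks of a given size
#'
#' @param m number of items
#' @param n mask size, `0 <= n <= m`
#' @return list of `choose(m, n)` integer vectors of hidden 1-based item
#'   indices, in lexicographic order (deterministic)
#' @export
enumerate_masks <- function(m, n) {
  if (n < 0 || n > m) stop("mask size must satisfy 0 <= n <= m")
  if (n == 0L) return(list(integer(0)))
  cols <- utils::combn(m, n)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

#' Apply a mask to one score record
#'
#' @param row numeric/integer vector of item scores
#' @param mask integer vector of 1-based indices to hide (possibly empty)
#' @return the row with hidden entries set to `NA`
#' @export
mask_sample <- function(row, mask) {
  if (length(mask)) row[mask] <- NA
  row
}

#' Per-item medians of a training split
#'
#' @param train dataset (item columns + optional `label`)
#' @return named numeric vector of per-item medians
#' @export
training_medians <- function(train) {
  items <- setdiff(names(train), "label")
  vapply(items, function(it) stats::median(train[[it]], na.rm = TRUE), numeric(1))
}

#' Median-impute missing entries
#'
#' Replaces every missing item score with that item's median computed on the
#' training split only; complete entries are never altered, so imputation is
#' the identity on complete data.
#'
#' @param masked dataset with possible `NA` entries in the item columns
#' @param medians named per-item medians from [training_medians()] on the
#'   training split
#' @return the completed dataset
#' @export
impute_median <- function(masked, medians) {
  items <- setdiff(names(masked), "label")
  missing_items <- setdiff(items, names(medians))
  if (length(missing_items))
    stop("no training median available for item(s): ",
         paste(missing_items, collapse = ", "))
  for (it in items) {
    idx <- is.na(masked[[it]])
    if (any(idx)) masked[[it]][idx] <- medians[[it]]
  }
  masked
}

#' Masked-augmentation scheme
#'
#' The default scheme is full combinatorial masking: every one of the `2^m`
#' masks (including the empty mask, i.e. the original row) is applied to
#' every training row — feasible at the ten-item scale where `2^10 = 1024`.
#' For larger catalogs a random-subsample scheme draws `count` distinct
#' non-empty masks (uniformly from the `2^m - 1` candidates, reproducibly
#' from `seed`) and always keeps the empty mask, giving `count + 1` variants
#' per row.
#'
#' @param sizes mask sizes to include; `NULL` means all sizes `0..m`
#' @param count number of random non-empty masks, or `NULL` for the full
#'   combinatorial scheme
#' @param seed seed for the random-subsample scheme
#' @return an `augmentation_scheme` list
#' @export
augmentation_scheme <- function(sizes = NULL, count = NULL, seed = 1L) {
  structure(list(sizes = sizes, count = count, seed = as.integer(seed)),
            class = "augmentation_scheme")
}

# materialize the scheme's masks for m items, as a list of index vectors
scheme_masks <- function(scheme, m) {
  sizes <- if (is.null(scheme$sizes)) 0:m else scheme$sizes
  if (any(sizes < 0) || any(sizes > m)) stop("mask sizes must lie in 0..m")
  all_masks <- unlist(lapply(sizes, enumerate_masks, m = m), recursive = FALSE)
  if (is.null(scheme$count)) return(all_masks)
  nonempty <- all_masks[vapply(all_masks, length, integer(1)) > 0L]
  count <- min(scheme$count, length(nonempty))
  set.seed(scheme$seed)
  c(list(integer(0)), nonempty[sample.int(length(nonempty), count)])
}

#' Augment a training set with masked copies
#'
#' Returns the original rows plus one masked copy per non-empty mask of the
#' scheme; labels are carried over unchanged.
#'
#' @param data complete training dataset (item columns + `label`)
#' @param scheme an [augmentation_scheme()]
#' @return the augmented dataset, `nrow(data) * n_masks` rows
#' @export
augment_training <- function(data, scheme = augmentation_scheme()) {
  items <- setdiff(names(data), "label")
  m <- length(items)
  masks <- scheme_masks(scheme, m)
  n <- nrow(data)
  scores <- as.matrix(data[items])
  big <- scores[rep(seq_len(n), times = length(masks)), , drop = FALSE]
  for (k in seq_along(masks)) {
    if (length(masks[[k]]))
      big[((k - 1) * n + 1):(k * n), masks[[k]]] <- NA
  }
  out <- as.data.frame(big)
  names(out) <- items
  out$label <- rep(data$label, times = length(masks))
  rownames(out) <- NULL
  out
}
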