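#' Item catalog
#'
#' An ordered list of clinical-instrument item identifiers. Every item is
#' scored on the ordinal scale \{0, 1, 2\} (0 = typical behaviour, 2 =
#' significantly atypical). The order of the items is fixed for the lifetime
#' of a trained policy: it determines which base-4 digit of the state key each
#' item occupies, so it is serialized alongside the policy.
#'
#' @param items character vector of unique item identifiers
#' @return an object of class `item_catalog`
#' @export
item_catalog <- function(items) {
  items <- as.character(items)
  if (length(items) < 1L) stop("catalog must contain at least one item")
  if (anyDuplicated(items)) stop("item identifiers must be unique")
  structure(list(items = items, m = length(items)), class = "item_catalog")
}

#' @export
print.item_catalog <- function(x, ...) {
  cat("Item catalog:", x$m, "items\n ", paste(x$items, collapse = ", "), "\n")
  invisible(x)
}

#' Default ten-item catalog
#'
#' The ten caregiver-interview items retained by the t-test screening,
#' ordered by decreasing discriminability.
#'
#' @param m number of items (identifiers are generated when `m != 10`)
#' @return an `item_catalog`
#' @export
default_catalog <- function(m = 10L) {
  adi <- c("ADI_35", "ADI_34", "ADI_68", "ADI_51", "ADI_33",
           "ADI_42", "ADI_59", "ADI_45", "ADI_57", "ADI_72")
  if (m == 10L) item_catalog(adi) else item_catalog(sprintf("item_%02d", seq_len(m)))
}

.check_codes <- function(codes) {
  if (!is.numeric(codes) || length(codes) < 1L)
    stop("observation must be a non-empty numeric vector of codes")
  if (anyNA(codes) || any(codes != floor(codes)) || any(codes < 0) || any(codes > 3))
    stop("invalid observation: every code must be an integer in {0,1,2,3}")
  as.integer(codes)
}

#' Encode a partial observation as a state key
#'
#' An observation vector holds one code per item: 0 when the item has not
#' been observed, and the raw score shifted by one (score k becomes code
#' k + 1) when it has, so that an observed score of 0 is distinct from
#' missing. The key is the observation read as a base-4 number with item i
#' (1-based) contributing `codes[i] * 4^(i-1)` (little-endian digit order);
#' the map is a bijection between observation vectors and `[0, 4^m)`.
#'
#' @param codes integer vector of codes in \{0,1,2,3\}, one per catalog item
#' @return a non-negative numeric scalar, the state key
#' @seealso [decode_state()], [apply_observation()]
#' @export
#' @examples
#' encode_state(rep(0, 10))          # empty state -> 0
#' encode_state(c(3, 0, 0))          # first item scored 2 -> 3
encode_state <- function(codes) {
  codes <- .check_codes(codes)
  sum(codes * 4^(seq_along(codes) - 1))
}

#' Decode a state key back to its observation vector
#'
#' Inverse of [encode_state()]: `decode_state(encode_state(v), length(v))`
#' recovers `v` for every valid observation vector.
#'
#' @param key non-negative state key, `0 <= key < 4^m`
#' @param m number of catalog items
#' @return integer vector of m codes
#' @export
decode_state <- function(key, m) {
  if (length(key) != 1L || is.na(key) || key < 0 || key != floor(key) || key >= 4^m)
    stop("state key out of range [0, 4^m)")
  codes <- integer(m)
  for (i in seq_len(m)) {
    codes[i] <- as.integer(key %% 4)
    key <- key %/% 4
  }
  codes
}

#' Record an observed item score in an observation vector
#'
#' Sets the code of `item_index` to `raw_score + 1`. The item must be
#' currently unobserved: the policy cannot repeat actions, so observing an
#' already-observed item is an error.
#'
#' @param codes observation vector (codes in \{0,1,2,3\})
#' @param item_index 1-based catalog position of the observed item
#' @param raw_score observed raw score in \{0,1,2\}
#' @return the updated observation vector
#' @export
apply_observation <- function(codes, item_index, raw_score) {
  codes <- .check_codes(codes)
  if (length(item_index) != 1L || item_index < 1L || item_index > length(codes))
    stop("item_index out of range")
  if (length(raw_score) != 1L || is.na(raw_score) || !raw_score %in% 0:2)
    stop("invalid score: raw_score must be in {0,1,2}")
  if (codes[item_index] != 0L)
    stop("repeat action: item ", item_index, " has already been observed")
  codes[item_index] <- as.integer(raw_score) + 1L
  codes
}

#' Number of observed items in an observation vector
#'
#' @param codes observation vector
#' @return count of nonzero codes
#' @export
observed_count <- function(codes) {
  codes <- .check_codes(codes)
  sum(codes != 0L)
}

# raw scores (0..2, NA = missing) -> codes (0 = missing, score + 1 otherwise)
scores_to_codes <- function(scores) {
  codes <- ifelse(is.na(scores), 0L, as.integer(scores) + 1L)
  .check_codes(codes)
}
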