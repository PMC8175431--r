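# Shared fixtures and independent oracles, all built in code.

# hand-built belief model: 1 item, two classes, explicit likelihoods.
# lik_a / lik_b: probability vectors over codes 0..3 for classes "A" (listed
# first = tie-break class) and "B".
toy_belief_1item <- function(lik_a, lik_b, prior = c(0.5, 0.5)) {
  loglik <- array(NA_real_, c(1, 4, 2),
                  dimnames = list("item_01", paste0("code", 0:3), c("A", "B")))
  loglik[1, , 1] <- log(lik_a)
  loglik[1, , 2] <- log(lik_b)
  structure(list(classes = c("A", "B"), log_prior = log(prior),
                 log_lik = loglik, smoothing = 1, prior = "manual",
                 items = "item_01"),
            class = "belief_model")
}

# m-item belief model with identical per-item likelihoods per class
toy_belief <- function(m, lik_a, lik_b, prior = c(0.5, 0.5),
                       items = sprintf("item_%02d", seq_len(m))) {
  loglik <- array(NA_real_, c(m, 4, 2),
                  dimnames = list(items, paste0("code", 0:3), c("A", "B")))
  for (i in seq_len(m)) {
    loglik[i, , 1] <- log(lik_a)
    loglik[i, , 2] <- log(lik_b)
  }
  structure(list(classes = c("A", "B"), log_prior = log(prior),
                 log_lik = loglik, smoothing = 1, prior = "manual",
                 items = items),
            class = "belief_model")
}

# degenerate belief models pinning the posterior at exactly 1, 1/2 or 0 so
# reward closed forms can be checked without tolerance
certain_model <- function(correct_class) {
  if (correct_class == "A")
    toy_belief_1item(c(1, 1, 1, 1) / 4, c(0, 0, 0, 0))
  else
    toy_belief_1item(c(0, 0, 0, 0), c(1, 1, 1, 1) / 4)
}
indifferent_model <- function() toy_belief_1item(rep(0.25, 4), rep(0.25, 4))

# small two-class dataset with one perfectly separating item
toy_separable_data <- function(n = 40, m = 3, seed = 5) {
  set.seed(seed)
  lab <- rep(c("ASD", "ADHD"), length.out = n)
  d <- as.data.frame(matrix(sample(0:2, n * m, TRUE), n, m))
  names(d) <- sprintf("item_%02d", seq_len(m))
  d$item_01 <- ifelse(lab == "ASD", 2L, 0L)
  d$label <- factor(lab, levels = c("ASD", "ADHD"))
  d
}

# Exact Q-function for a single fixed sample by exhaustive backward
# induction over observed-item subsets (the environment is deterministic:
# transitions and rewards are functions of the subset alone). Returns a list
# keyed by state key holding the vector of exact action values (NA for
# unavailable ask-actions). Independent of the Q-learning code path: uses
# only the belief/reward functions and direct recursion.
exact_q_backward <- function(g, scores, label, params, gamma) {
  m <- length(scores)
  codes_of <- function(subset) {
    codes <- integer(m)
    codes[subset] <- scores[subset] + 1L
    codes
  }
  memo_v <- new.env(parent = emptyenv())   # subset -> optimal value
  memo_q <- list()
  subset_key <- function(subset) paste(sort(subset), collapse = ",")

  q_of <- function(subset) {
    codes <- codes_of(subset)
    q <- rep(NA_real_, m + 1L)
    for (i in setdiff(seq_len(m), subset)) {
      nxt <- sort(c(subset, i))
      r <- local_reward(g, codes_of(nxt), label, params$beta)
      q[i] <- r + gamma * v_of(nxt)
    }
    q[m + 1L] <- final_reward(g, codes, label, length(subset), params)
    q
  }
  v_of <- function(subset) {
    key <- subset_key(subset)
    if (!is.null(memo_v[[key]])) return(memo_v[[key]])
    v <- max(q_of(subset), na.rm = TRUE)
    memo_v[[key]] <- v
    v
  }

  subsets <- unlist(lapply(0:m, function(n) enumerate_masks(m, n)),
                    recursive = FALSE)
  out <- list()
  for (subset in subsets) {
    key <- format(encode_state(codes_of(subset)), scientific = FALSE)
    out[[key]] <- q_of(subset)
  }
  out
}

# default-condition experiment used by the robustness and dispersion
# acceptance checks; memoized so the suite pays for it once
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_experiment <- function() {
  if (is.null(.acceptance_cache$res)) {
    data <- generate_dataset(generator_config(seed = 20260101))
    .acceptance_cache$res <- run_experiment(data, k = 10, seed = 9)
  }
  .acceptance_cache$res
}
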