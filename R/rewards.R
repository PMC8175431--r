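# Reward shaping for the diagnostic policy. Two signals drive learning:
# a local reward after each query, proportional to how far the belief in the
# true class has moved past indifference, and a terminal reward at PREDICT
# that pays a brevity bonus for committing after fewer questions (or -1 for
# a wrong prediction).

#' Reward parameters
#'
#' @param beta reward scale, > 0; the local reward lies in \[-beta, beta\]
#'   and a correct prediction earns at least beta
#' @param C brevity-bonus coefficient, >= 0; a correct prediction after h of
#'   l possible questions earns `beta + C * (1 - h/l)`
#' @param l total number of items available to query (catalog size)
#' @return a `reward_params` list
#' @export
reward_params <- function(beta = 1, C = 1, l = 10L) {
  if (beta <= 0) stop("beta must be > 0")
  if (C < 0) stop("C must be >= 0")
  if (l < 1L) stop("l must be >= 1")
  structure(list(beta = beta, C = C, l = as.integer(l)), class = "reward_params")
}

#' Local (per-query) reward
#'
#' `beta * (2 * (belief[y] - 1/2))`: zero at indifference, +beta when the
#' belief is certain of the true class, -beta when certain of the wrong one.
#' Evaluated on the state the agent transitions into after a query.
#'
#' @param model belief model G
#' @param codes observation vector after the query
#' @param y true label (character, one of `model$classes`)
#' @param beta reward scale
#' @return numeric scalar in \[-beta, beta\]
#' @export
local_reward <- function(model, codes, y, beta = 1) {
  b <- belief(model, codes)
  if (!y %in% model$classes) stop("unknown label: ", y)
  beta * (2 * (b[[y]] - 0.5))
}

#' Final (terminal) reward at PREDICT
#'
#' If the belief's argmax equals the true label the agent earns
#' `beta + C * (1 - h/l)` — the brevity bonus is largest when few of the l
#' items were queried and vanishes at h = l; otherwise the reward is -1
#' regardless of h.
#'
#' @param model belief model G
#' @param codes observation vector at prediction time
#' @param y true label
#' @param h number of queries made in the episode, `0 <= h <= l`
#' @param params a [reward_params()]
#' @return numeric scalar
#' @export
final_reward <- function(model, codes, y, h, params = reward_params()) {
  if (h < 0 || h > params$l) stop("h must satisfy 0 <= h <= l")
  if (!y %in% model$classes) stop("unknown label: ", y)
  if (predict_label(model, codes) == y) params$beta + params$C * (1 - h / params$l)
  else -1
}
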