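# The tabular Q-learning agent. Actions 1..m query catalog items; action
# m + 1 (PREDICT) terminates the episode by submitting the belief's argmax
# as the diagnosis. The Q-table is sparse: unseen (state, action) pairs read
# as 0. Episode simulation and batch training run in compiled code; the
# functions here provide the same semantics step by step in R for episode
# traces, single-sample explanation, and testing.

PREDICT <- function(m) m + 1L

#' Training configuration for the Q-learning policy
#'
#' Defaults are the study conditions: exploration probability epsilon = 0.2,
#' discount gamma = 0.99, learning rate alpha = 0.01, and early stopping
#' once the mean development-set episode reward has failed to improve for
#' more than 30 iterations (an iteration is one pass over the shuffled
#' training samples, one episode each).
#'
#' @param epsilon exploration probability in \[0,1)
#' @param gamma discount factor in (0,1\]
#' @param alpha learning rate in (0,1\]
#' @param patience early-stopping window (iterations without dev improvement
#'   tolerated before stopping); `patience = 0` stops at the first
#'   non-improving iteration
#' @param max_iterations hard cap on training iterations
#' @param min_iterations warm-up before the early stopper starts tracking:
#'   at a learning rate of 0.01 the value of querying propagates up the
#'   state space over hundreds of passes, and the first iterations' greedy
#'   policy (driven by tie-breaking on a zero-initialized table) is not a
#'   meaningful dev-reward baseline to measure improvement against
#' @param dev_fraction fraction of the training split held out (stratified)
#'   as the development set; `0` disables early stopping and trains for
#'   `max_iterations`
#' @param seed integer seed, or `NULL` to use the current RNG state
#' @return a `train_config` list
#' @export
train_config <- function(epsilon = 0.2, gamma = 0.99, alpha = 0.01,
                         patience = 30L, max_iterations = 3000L,
                         min_iterations = 1000L, dev_fraction = 0.1,
                         seed = NULL) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0,1)")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0,1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0,1]")
  if (patience < 0) stop("patience must be >= 0")
  if (dev_fraction < 0 || dev_fraction >= 1) stop("dev_fraction must lie in [0,1)")
  if (min_iterations < 0) stop("min_iterations must be >= 0")
  structure(list(epsilon = epsilon, gamma = gamma, alpha = alpha,
                 patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations),
                 min_iterations = as.integer(min_iterations),
                 dev_fraction = dev_fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "train_config")
}

#' Create an empty sparse Q-table
#'
#' @param m number of catalog items (so each state has m + 1 action values)
#' @return an environment-backed sparse table; unseen states read as zeros
#' @export
new_qtable <- function(m) {
  q <- new.env(parent = emptyenv())
  attr(q, "m") <- as.integer(m)
  q
}

#' Read a state's action values from a Q-table
#'
#' @param q a [new_qtable()]
#' @param state state key
#' @return numeric vector of m + 1 action values (zeros if unseen)
#' @export
q_values <- function(q, state) {
  key <- format(state, scientific = FALSE)
  if (exists(key, envir = q, inherits = FALSE)) get(key, envir = q)
  else numeric(attr(q, "m") + 1L)
}

q_assign <- function(q, state, values) {
  assign(format(state, scientific = FALSE), values, envir = q)
}

#' Actions available in a state
#'
#' Ask-actions for items not yet acted on, plus PREDICT (action m + 1).
#' PREDICT is always available — including from the empty state; the policy
#' learns to avoid premature prediction rather than being barred from it.
#' By default an item counts as acted on when its digit is nonzero; during
#' masked-input evaluation an explicit `acted` flag vector tracks queries
#' that consumed the action but revealed nothing.
#'
#' @param codes observation vector
#' @param acted logical vector of consumed ask-actions (default: observed
#'   items)
#' @return integer vector of available action indices, ascending
#' @export
available_actions <- function(codes, acted = codes != 0L) {
  codes <- .check_codes(codes)
  m <- length(codes)
  c(which(!acted), PREDICT(m))
}

#' Epsilon-greedy action selection
#'
#' With probability epsilon a uniform draw from the available actions;
#' otherwise the available action with the largest Q-value, ties broken by
#' the lowest action index so greedy rollouts are deterministic.
#'
#' @param q Q-table
#' @param state state key
#' @param avail integer vector of available actions (non-empty, ascending)
#' @param epsilon exploration probability
#' @return the selected action index
#' @export
select_action <- function(q, state, avail, epsilon = 0) {
  if (!length(avail)) stop("no available actions")
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    avail[sample.int(length(avail), 1L)]
  } else {
    vals <- q_values(q, state)[avail]
    avail[which.max(vals)]    # which.max -> first max = lowest action index
  }
}

#' Temporal-difference update of one Q-table entry
#'
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s', a') - Q(s,a))`,
#' with the future term restricted to the successor's available actions and
#' dropped entirely on terminal transitions.
#'
#' @param q Q-table (updated in place)
#' @param s,a state key and action taken
#' @param r observed reward
#' @param s_next successor state key
#' @param avail_next available actions in the successor state
#' @param alpha learning rate
#' @param gamma discount factor
#' @param terminal whether the transition ended the episode
#' @return the updated Q(s,a) entry, invisibly
#' @export
q_update <- function(q, s, a, r, s_next, avail_next, alpha, gamma,
                     terminal = FALSE) {
  vals <- q_values(q, s)
  future <- if (terminal) 0 else max(q_values(q, s_next)[avail_next])
  vals[a] <- vals[a] + alpha * (r + gamma * future - vals[a])
  q_assign(q, s, vals)
  invisible(vals[a])
}

#' Simulate one diagnostic episode
#'
#' Starts at the empty state; each ask-action reveals the sample's shifted
#' score (or nothing, leaving the digit at 0, when that item is masked) and
#' yields the local reward evaluated on the resulting state; PREDICT
#' terminates with the final reward. In `train_mode` every transition
#' triggers a TD update and actions are epsilon-greedy; otherwise the
#' rollout is greedy and the table is untouched.
#'
#' @param q Q-table
#' @param g belief model
#' @param scores the sample's raw item scores (`NA` = masked)
#' @param label the sample's true label
#' @param params [reward_params()]
#' @param cfg [train_config()] (epsilon/alpha/gamma are read from it)
#' @param train_mode perform updates and explore
#' @param record_branches record, at each ask step, the beliefs that each of
#'   the three possible responses would have produced (for trace export)
#' @return an `episode_trace`: data.frame of steps plus attributes
#'   (`total_reward`, `prediction`, `questions`, per-step Q-value and
#'   belief lists)
#' @export
run_episode <- function(q, g, scores, label, params = reward_params(l = length(scores)),
                        cfg = train_config(), train_mode = FALSE,
                        record_branches = FALSE) {
  m <- length(scores)
  codes <- integer(m)
  acted <- logical(m)
  h <- 0L
  total <- 0
  y <- as.character(label)
  eps <- if (train_mode) cfg$epsilon else 0
  steps <- list()
  branches <- list()
  beliefs <- list()
  q_steps <- list()

  repeat {
    s <- encode_state(codes)
    avail <- available_actions(codes, acted)
    a <- select_action(q, s, avail, eps)
    q_steps[[length(q_steps) + 1L]] <- q_values(q, s)

    if (a == PREDICT(m)) {
      r <- final_reward(g, codes, y, h, params)
      if (train_mode) q_update(q, s, a, r, s, integer(0), cfg$alpha, cfg$gamma,
                               terminal = TRUE)
      total <- total + r
      steps[[length(steps) + 1L]] <- data.frame(
        state = s, action = "PREDICT", observation = predict_label(g, codes),
        reward = r, stringsAsFactors = FALSE)
      beliefs[[length(beliefs) + 1L]] <- belief(g, codes)
      branches[length(branches) + 1L] <- list(NULL)
      break
    }

    acted[a] <- TRUE
    h <- h + 1L
    codes_next <- codes
    if (!is.na(scores[a])) codes_next <- apply_observation(codes, a, scores[a])
    r <- local_reward(g, codes_next, y, params$beta)
    if (train_mode) {
      avail_next <- available_actions(codes_next, acted)
      q_update(q, s, a, r, encode_state(codes_next), avail_next,
               cfg$alpha, cfg$gamma)
    }
    total <- total + r
    steps[[length(steps) + 1L]] <- data.frame(
      state = s, action = g$items[a],
      observation = as.character(codes_next[a]), reward = r,
      stringsAsFactors = FALSE)
    beliefs[[length(beliefs) + 1L]] <- belief(g, codes_next)
    branches[length(branches) + 1L] <- list(if (record_branches) {
      lapply(0:2, function(sc) {
        cn <- apply_observation(codes, a, sc)
        list(score = sc, state = encode_state(cn), belief = belief(g, cn))
      })
    })
    codes <- codes_next
  }

  trace <- do.call(rbind, steps)
  structure(trace, class = c("episode_trace", "data.frame"),
            total_reward = total,
            prediction = predict_label(g, codes),
            questions = h,
            final_codes = codes,
            q_steps = q_steps,
            beliefs = beliefs,
            branches = branches)
}

#' Train the diagnostic policy by episode simulation
#'
#' Carves a stratified development split from the training data, then
#' repeatedly sweeps the remaining samples in shuffled order, running one
#' epsilon-greedy training episode per sample with TD updates. After each
#' sweep the mean greedy episode reward on the development set is recorded;
#' training stops at `max_iterations` or once that reward has not improved
#' for more than `patience` iterations, and the table from the best
#' development iteration is returned.
#'
#' @param train complete training dataset (item columns + `label`)
#' @param g belief model fitted on the (masked-augmented) training split
#' @param params [reward_params()]; `l` defaults to the catalog size
#' @param cfg [train_config()]
#' @return a `q_policy` object: sparse Q-table (states + value matrix),
#'   catalog, belief model, configs, dev-reward history and best iteration
#' @export
train_policy <- function(train, g, params = NULL, cfg = train_config()) {
  items <- g$items
  if (!all(items %in% names(train))) stop("training data lacks catalog items")
  m <- length(items)
  if (is.null(params)) params <- reward_params(l = m)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (nrow(train) < 2L) stop("training split is too small")

  y <- match(as.character(train$label), g$classes) - 1L
  if (anyNA(y)) stop("training labels outside the belief model's classes")

  n <- nrow(train)
  idx <- seq_len(n)
  if (cfg$dev_fraction > 0) {
    dev <- unlist(lapply(split(idx, train$label), function(ix) {
      k <- max(1L, round(length(ix) * cfg$dev_fraction))
      sample(ix, k)
    }), use.names = FALSE)
    tr <- setdiff(idx, dev)
    if (!length(tr)) stop("dev split consumed all training samples")
  } else {
    dev <- integer(0)
    tr <- idx
  }

  scores <- as.matrix(train[items])
  storage.mode(scores) <- "integer"
  fit <- .cpp_train_policy(scores, y, as.numeric(g$log_lik), g$log_prior,
                           tr - 1L, dev - 1L,
                           params$beta, params$C, cfg$epsilon, cfg$gamma,
                           cfg$alpha, cfg$patience, cfg$max_iterations,
                           cfg$min_iterations)
  colnames(fit$values) <- c(items, "PREDICT")
  structure(list(catalog = item_catalog(items),
                 states = fit$states, q = fit$values,
                 params = params, config = cfg, belief = g,
                 history = fit$history, best_iter = fit$best_iter,
                 n_iterations = fit$n_iterations,
                 dev_index = dev),
            class = "q_policy")
}

#' @export
print.q_policy <- function(x, ...) {
  cat("Q-learning diagnostic policy:", x$catalog$m, "items,",
      length(x$states), "visited states;",
      x$n_iterations, "iterations (best dev iteration", x$best_iter, ")\n")
  invisible(x)
}

# materialize a q_policy's sparse table as an R Q-table environment
policy_qtable <- function(policy) {
  q <- new_qtable(policy$catalog$m)
  for (r in seq_along(policy$states))
    q_assign(q, policy$states[r], unname(policy$q[r, ]))
  q
}

#' Greedy policy evaluation on (possibly masked) samples
#'
#' Runs one greedy episode per row. Missing entries stay encoded as 0:
#' asking a masked item consumes the action but reveals nothing, and the
#' final prediction is the belief argmax at the terminal state.
#'
#' @param policy a trained [train_policy()] object
#' @param rows data.frame or matrix of raw item scores (`NA` = masked)
#' @param masked_items `"askable"` (default: querying a masked item consumes
#'   the action and reveals nothing) or `"excluded"` (sensitivity option:
#'   masked items are removed from the action space)
#' @return list with `pred` (factor of predicted labels), `questions`
#'   (ask-actions consumed per row)
#' @export
evaluate_policy <- function(policy, rows,
                            masked_items = c("askable", "excluded")) {
  masked_items <- match.arg(masked_items)
  items <- policy$catalog$items
  g <- policy$belief
  if (is.data.frame(rows)) rows <- as.matrix(rows[items])
  storage.mode(rows) <- "integer"
  out <- .cpp_eval_policy(policy$states, policy$q, rows,
                          as.numeric(g$log_lik), g$log_prior,
                          masked_items == "excluded")
  list(pred = factor(g$classes[out$pred + 1L], levels = g$classes),
       questions = out$questions)
}

#' Policy feature importance from the empty state
#'
#' The Q-values of the ask-actions at state 0 are the policy's priority
#' order when nothing is known yet. They are shifted by their minimum and
#' normalized to sum to 1 so they are comparable with tree impurity
#' importances; the population variance and range of the normalized vector
#' summarize how evenly the policy spreads its attention.
#'
#' @param policy a trained policy
#' @return list with `importance` (named, sums to 1), `variance`
#'   (population variance) and `range`
#' @export
policy_feature_importance <- function(policy) {
  m <- policy$catalog$m
  r <- which(policy$states == 0)
  v <- if (length(r)) unname(policy$q[r[1], seq_len(m)]) else numeric(m)
  v <- v - min(v)
  imp <- if (sum(v) == 0) rep(1 / m, m) else v / sum(v)
  names(imp) <- policy$catalog$items
  list(importance = imp,
       variance = mean((imp - mean(imp))^2),
       range = max(imp) - min(imp))
}

#' Export an episode trace as a decision-graph document
#'
#' Serializable graph of the states visited, the action chosen at each, and
#' (when the trace recorded them) all three possible response branches with
#' the beliefs they would have produced, plus the underlying Q-values — the
#' numbers behind a decision-flow rendering of the policy.
#'
#' @param trace an `episode_trace` from [run_episode()]
#' @param catalog the policy's [item_catalog()]
#' @return a list with `nodes` and `edges`, ready for [jsonlite::toJSON()]
#' @export
export_trace <- function(trace, catalog) {
  m <- catalog$m
  q_steps <- attr(trace, "q_steps")
  branches <- attr(trace, "branches")
  nodes <- lapply(seq_len(nrow(trace)), function(i) {
    list(id = trace$state[i],
         codes = decode_state(trace$state[i], m),
         action = trace$action[i],
         q = stats::setNames(q_steps[[i]], c(catalog$items, "PREDICT")),
         reward = trace$reward[i])
  })
  edges <- list()
  for (i in seq_len(nrow(trace))) {
    if (trace$action[i] == "PREDICT") next
    br <- branches[[i]]
    if (is.null(br)) {
      to <- if (i < nrow(trace)) trace$state[i + 1] else NA
      edges[[length(edges) + 1L]] <- list(
        from = trace$state[i], to = to, action = trace$action[i],
        observation = trace$observation[i], taken = TRUE)
    } else {
      taken_code <- suppressWarnings(as.integer(trace$observation[i]))
      for (b in br) {
        edges[[length(edges) + 1L]] <- list(
          from = trace$state[i], to = b$state, action = trace$action[i],
          score = b$score, belief = b$belief,
          taken = identical(b$score + 1L, taken_code))
      }
    }
  }
  list(nodes = nodes, edges = edges,
       prediction = attr(trace, "prediction"),
       total_reward = attr(trace, "total_reward"))
}

#' Serialize a trained policy (catalog, Q-table, belief model) to JSON
#'
#' @param policy a `q_policy`
#' @param path output path
#' @export
save_policy <- function(policy, path) {
  g <- policy$belief
  doc <- list(
    catalog = policy$catalog$items,
    states = format(policy$states, scientific = FALSE, trim = TRUE),
    q = unname(policy$q),
    params = unclass(policy$params),
    config = unclass(policy$config),
    history = policy$history,
    best_iter = policy$best_iter,
    belief = list(classes = g$classes, log_prior = g$log_prior,
                  log_lik = as.numeric(g$log_lik), smoothing = g$smoothing,
                  items = g$items))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a policy saved by [save_policy()]
#'
#' @param path JSON path
#' @return a `q_policy`
#' @export
load_policy <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- doc$belief$items
  m <- length(items)
  g <- structure(list(classes = doc$belief$classes,
                      log_prior = doc$belief$log_prior,
                      log_lik = array(doc$belief$log_lik, c(m, 4L, 2L),
                                      dimnames = list(items, paste0("code", 0:3),
                                                      doc$belief$classes)),
                      smoothing = doc$belief$smoothing, items = items),
                 class = "belief_model")
  qmat <- matrix(as.numeric(doc$q), ncol = m + 1L)
  colnames(qmat) <- c(items, "PREDICT")
  cfg <- doc$config
  structure(list(catalog = item_catalog(doc$catalog),
                 states = as.numeric(doc$states), q = qmat,
                 params = do.call(reward_params, doc$params),
                 config = train_config(cfg$epsilon, cfg$gamma, cfg$alpha,
                                       cfg$patience, cfg$max_iterations,
                                       cfg$min_iterations, cfg$dev_fraction,
                                       cfg$seed),
                 belief = g, history = doc$history,
                 best_iter = doc$best_iter,
                 n_iterations = length(doc$history)),
            class = "q_policy")
}
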