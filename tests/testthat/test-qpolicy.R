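# small helpers for building policies by hand
manual_policy <- function(m, states, qmat, g = NULL,
                          items = sprintf("item_%02d", seq_len(m))) {
  if (is.null(g)) g <- toy_belief(m, rep(0.25, 4), c(0.4, 0.3, 0.2, 0.1),
                                  items = items)
  colnames(qmat) <- c(items, "PREDICT")
  structure(list(catalog = item_catalog(items), states = states, q = qmat,
                 params = reward_params(l = m), config = train_config(),
                 belief = g, history = numeric(0), best_iter = 0,
                 n_iterations = 0),
            class = "q_policy")
}

test_that("available actions exclude acted items and always include PREDICT", {
  expect_equal(available_actions(rep(0L, 10)), c(1:10, 11L))
  expect_equal(available_actions(rep(1L, 10)), 11L)
  obs <- apply_observation(rep(0L, 10), 4, 1)
  expect_false(4 %in% available_actions(obs))
  # an acted-but-unobserved item (masked query) is excluded via the flag
  acted <- c(TRUE, rep(FALSE, 9))
  expect_false(1 %in% available_actions(rep(0L, 10), acted))
})

test_that("action selection is greedy with deterministic ties, uniform when exploring", {
  q <- new_qtable(2)
  qdiagnose:::q_assign(q, 0, c(0.3, 0.1, 0.2))
  expect_equal(select_action(q, 0, 1:3, epsilon = 0), 1L)
  qdiagnose:::q_assign(q, 0, c(0.1, 0.1, 0.1))
  expect_equal(select_action(q, 0, 1:3, epsilon = 0), 1L)  # tie -> lowest
  expect_equal(select_action(q, 0, 2:3, epsilon = 0), 2L)
  expect_error(select_action(q, 0, integer(0), 0))

  set.seed(99)
  draws <- replicate(6000, select_action(q, 0, 1:3, epsilon = 1))
  tab <- table(factor(draws, levels = 1:3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("TD updates follow the Q-learning recursion", {
  q <- new_qtable(1)
  # fresh table, terminal transition, r = 1, alpha = 0.01 -> entry 0.01
  q_update(q, 0, 2, r = 1, s_next = 0, avail_next = integer(0),
           alpha = 0.01, gamma = 0.99, terminal = TRUE)
  expect_equal(q_values(q, 0)[2], 0.01)
  # zero TD error leaves the entry untouched
  q2 <- new_qtable(1)
  q_update(q2, 0, 1, r = 0, s_next = 5, avail_next = 1:2,
           alpha = 0.5, gamma = 0.9)
  expect_equal(q_values(q2, 0)[1], 0)

  # two-state deterministic chain: repeated updates reach the value-iteration
  # fixed point Q*(B) = r2, Q*(A) = r1 + gamma * Q*(B)
  r1 <- 0.3; r2 <- 1; gamma <- 0.9
  qc <- new_qtable(0)              # 1 action per state here
  attr(qc, "m") <- 0L              # vectors of length 1
  for (i in 1:2000) {
    q_update(qc, "A", 1, r1, "B", 1, alpha = 0.1, gamma = gamma)
    q_update(qc, "B", 1, r2, "B", 1, alpha = 0.1, gamma = gamma,
             terminal = TRUE)
  }
  expect_equal(q_values(qc, "B")[1], r2, tolerance = 1e-6)
  expect_equal(q_values(qc, "A")[1], r1 + gamma * r2, tolerance = 1e-6)
})

test_that("episodes terminate, respect no-repeat, and account rewards exactly", {
  m <- 2
  g <- toy_belief(m, c(0.25, 0.5, 0.15, 0.1), c(0.25, 0.1, 0.15, 0.5))
  params <- reward_params(beta = 1, C = 1, l = m)
  cfg <- train_config()

  # table that prefers ask-2 then PREDICT
  q <- new_qtable(m)
  qdiagnose:::q_assign(q, 0, c(0.1, 0.9, 0.2))
  qdiagnose:::q_assign(q, 4, c(-1, -1, 5))   # state after item-2 scores 0
  scores <- c(1L, 0L)
  tr <- run_episode(q, g, scores, "A", params, cfg)
  expect_s3_class(tr, "episode_trace")
  expect_equal(tr$action[1], "item_02")
  expect_lte(nrow(tr), m + 1)
  expect_equal(tr$action[nrow(tr)], "PREDICT")

  # manual reward bookkeeping for the recorded path
  codes1 <- apply_observation(c(0L, 0L), 2, scores[2])
  r1 <- local_reward(g, codes1, "A", 1)
  r2 <- final_reward(g, codes1, "A", h = 1, params)
  expect_equal(tr$reward, c(r1, r2))
  expect_equal(attr(tr, "total_reward"), r1 + r2)
  expect_equal(attr(tr, "questions"), 1)

  # PREDICT-dominant table gives a one-step episode with final reward only
  q2 <- new_qtable(m)
  qdiagnose:::q_assign(q2, 0, c(0, 0, 5))
  tr2 <- run_episode(q2, g, scores, "A", params, cfg)
  expect_equal(nrow(tr2), 1)
  expect_equal(attr(tr2, "questions"), 0)
  expect_equal(tr2$reward, final_reward(g, c(0L, 0L), "A", 0, params))

  # termination within m + 1 steps for arbitrary tables and samples
  set.seed(12)
  for (i in 1:20) {
    mm <- sample(2:6, 1)
    gg <- toy_belief(mm, rep(0.25, 4), c(0.4, 0.3, 0.2, 0.1))
    qq <- new_qtable(mm)
    qdiagnose:::q_assign(qq, 0, stats::runif(mm + 1))
    sc <- sample(0:2, mm, TRUE)
    sc[sample(mm, sample(0:mm, 1))] <- NA   # masked entries stay askable
    trr <- run_episode(qq, gg, sc, "B", reward_params(l = mm), cfg,
                       train_mode = TRUE)
    expect_lte(nrow(trr), mm + 1)
    expect_equal(trr$action[nrow(trr)], "PREDICT")
    expect_lte(attr(trr, "questions"), mm)
    expect_equal(anyDuplicated(trr$action), 0L)
  }
})

test_that("compiled greedy evaluation matches the R episode runner", {
  d <- toy_separable_data(n = 60, m = 4, seed = 21)
  aug <- augment_training(d, augmentation_scheme(count = 15, seed = 1))
  g <- fit_belief(aug)
  pol <- train_policy(d, g, cfg = train_config(max_iterations = 150,
                                               min_iterations = 0,
                                               patience = 150, seed = 5))
  q <- qdiagnose:::policy_qtable(pol)
  items <- pol$catalog$items
  rows <- as.matrix(d[items])
  rows[3, 2] <- NA
  rows[4, ] <- NA
  out <- evaluate_policy(pol, rows)
  for (i in c(1:5, 10, 20)) {
    tr <- run_episode(q, g, rows[i, ], d$label[i], pol$params, pol$config)
    expect_equal(as.character(out$pred[i]), attr(tr, "prediction"))
    expect_equal(out$questions[i], attr(tr, "questions"))
  }
  # a fully masked row still terminates with a prediction
  expect_false(is.na(out$pred[4]))

  # sensitivity mode: masked items leave the action space, so questions are
  # bounded by the number of observable items and predictions are unchanged
  # on complete rows
  out_ex <- evaluate_policy(pol, rows, masked_items = "excluded")
  observable <- rowSums(!is.na(rows))
  expect_true(all(out_ex$questions <= observable))
  complete <- which(observable == ncol(rows))
  expect_identical(out_ex$pred[complete], out$pred[complete])
})

test_that("training is seed-deterministic and honors patience contracts", {
  d <- toy_separable_data(n = 50, m = 3, seed = 2)
  g <- fit_belief(augment_training(d, augmentation_scheme(count = 7, seed = 1)))
  cfg <- train_config(max_iterations = 60, min_iterations = 0, seed = 7)
  p1 <- train_policy(d, g, cfg = cfg)
  p2 <- train_policy(d, g, cfg = cfg)
  expect_identical(p1$states, p2$states)
  expect_identical(p1$q, p2$q)
  expect_identical(p1$history, p2$history)
  expect_lte(p1$n_iterations, 60)

  # patience = 0 stops at the first non-improving iteration after warm-up
  cfg0 <- train_config(max_iterations = 200, min_iterations = 0,
                       patience = 0, seed = 7)
  p0 <- train_policy(d, g, cfg = cfg0)
  expect_lt(p0$n_iterations, 200)

  # dev_fraction = 0 disables early stopping entirely
  pfull <- train_policy(d, g, cfg = train_config(max_iterations = 25,
                                                 dev_fraction = 0, seed = 1))
  expect_equal(pfull$n_iterations, 25)
})

test_that("empty-state importances are shift-normalized with exact dispersion", {
  qmat <- matrix(c(0, 1, 0.5), nrow = 1)
  pol <- manual_policy(2, states = 0, qmat = qmat)
  imp <- policy_feature_importance(pol)
  expect_equal(unname(imp$importance), c(0, 1))
  expect_equal(imp$range, 1)
  expect_equal(imp$variance, 0.25)
  expect_equal(sum(imp$importance), 1)

  # all-equal Q(0, .) collapses to the uniform vector
  pol2 <- manual_policy(4, states = 0, qmat = matrix(rep(2, 5), nrow = 1))
  imp2 <- policy_feature_importance(pol2)
  expect_equal(unname(imp2$importance), rep(0.25, 4))
  expect_equal(imp2$variance, 0)
  expect_equal(imp2$range, 0)
})

test_that("policies survive a JSON round trip bit-for-bit in behavior", {
  d <- toy_separable_data(n = 40, m = 3, seed = 9)
  g <- fit_belief(augment_training(d, augmentation_scheme(count = 7, seed = 4)))
  pol <- train_policy(d, g, cfg = train_config(max_iterations = 80,
                                               min_iterations = 0, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_policy(pol, path)
  pol2 <- load_policy(path)
  expect_equal(pol2$catalog$items, pol$catalog$items)
  expect_equal(sort(pol2$states), sort(pol$states))
  rows <- as.matrix(d[pol$catalog$items])
  e1 <- evaluate_policy(pol, rows)
  e2 <- evaluate_policy(pol2, rows)
  expect_identical(e1$pred, e2$pred)
  expect_identical(e1$questions, e2$questions)
})

test_that("trace export mirrors the episode path with full response branches", {
  m <- 3
  g <- toy_belief(m, c(0.25, 0.5, 0.15, 0.1), c(0.25, 0.1, 0.15, 0.5))
  q <- new_qtable(m)
  qdiagnose:::q_assign(q, 0, c(2, 1, 0.5, 0.2))
  tr <- run_episode(q, g, c(2L, 0L, 1L), "B", reward_params(l = m),
                    train_config(), record_branches = TRUE)
  doc <- export_trace(tr, item_catalog(sprintf("item_%02d", 1:m)))
  expect_length(doc$nodes, nrow(tr))
  # graph path matches the recorded state sequence
  expect_equal(vapply(doc$nodes, `[[`, numeric(1), "id"), tr$state)
  ask_steps <- sum(tr$action != "PREDICT")
  expect_length(doc$edges, 3 * ask_steps)   # three possible scores per ask
  taken <- Filter(function(e) isTRUE(e$taken), doc$edges)
  expect_length(taken, ask_steps)
  # the successor of each taken edge is the next recorded state
  for (i in seq_len(ask_steps)) {
    expect_equal(taken[[i]]$from, tr$state[i])
    expect_equal(taken[[i]]$to, tr$state[i + 1])
  }

  # a one-step PREDICT trace exports a single-node graph
  qp <- new_qtable(m)
  qdiagnose:::q_assign(qp, 0, c(0, 0, 0, 9))
  tr1 <- run_episode(qp, g, c(2L, 0L, 1L), "B", reward_params(l = m),
                     train_config(), record_branches = TRUE)
  doc1 <- export_trace(tr1, item_catalog(sprintf("item_%02d", 1:m)))
  expect_length(doc1$nodes, 1)
  expect_length(doc1$edges, 0)
})
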