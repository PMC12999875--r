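test_that("colour and switch predictors are circular hue distances", {
  expect_equal(colour_predictor(24, 24), 0)
  expect_equal(colour_predictor(32, 24), 8)
  expect_equal(colour_predictor(4, 24), circular_distance(4, 24))  # wraps to 20
  expect_equal(switch_predictor(10, 14), 4)
  expect_equal(switch_predictor(2, 47), 3)
  expect_error(switch_predictor(2, NA), "previous")
})

test_that("proximity predictor is Euclidean distance on the unit square", {
  expect_equal(distance_predictor(0, 0, 0, 0), 0)
  expect_equal(distance_predictor(1, 0, 0, 0), 1)
  expect_equal(distance_predictor(1, 1, 0, 0), sqrt(2))
})

test_that("direction predictor hits its three geometric anchors", {
  # penultimate (0,0) -> previous (1,0); candidates ahead, above, behind
  expect_equal(direction_predictor(2, 0, 1, 0, 0, 0), 0)
  expect_equal(direction_predictor(1, 1, 1, 0, 0, 0), 0.5)
  expect_equal(direction_predictor(0, 0, 1, 0, 0, 0), 1)
  # degenerate zero-length travel vector falls back to the midpoint
  expect_equal(direction_predictor(1, 0, 1, 0, 0, 0), 0.5)
})

test_that("spatial predictors are invariant to rigid motions", {
  set.seed(42)
  for (rep in 1:20) {
    pts <- matrix(runif(8), 4, 2)  # candidate, prev, penult, spare
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    shift <- runif(2, -3, 3)
    tp <- t(R %*% t(pts)) + rep(shift, each = 4)
    psi0 <- direction_predictor(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2],
                                pts[3, 1], pts[3, 2])
    psi1 <- direction_predictor(tp[1, 1], tp[1, 2], tp[2, 1], tp[2, 2],
                                tp[3, 1], tp[3, 2])
    expect_equal(psi0, psi1, tolerance = 1e-10)
    d0 <- distance_predictor(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2])
    d1 <- distance_predictor(tp[1, 1], tp[1, 2], tp[2, 1], tp[2, 2])
    expect_equal(d0, d1, tolerance = 1e-10)
  }
})

test_that("selection weights express the exponential biases", {
  disp <- toy_display()
  st1 <- choice_state(disp$items, mu = 24)
  expect_equal(selection_weights(st1, model_parameters()), rep(1, 4))
  # proximity only: the nearer item gets the larger weight
  items <- data.frame(item_id = 1:2, hue = c(24, 24),
                      x = c(0.1, 0.5), y = c(0, 0))
  prev <- data.frame(item_id = 3, hue = 24, x = 0, y = 0)
  st2 <- choice_state(items, mu = 24, prev = prev)
  w <- selection_weights(st2, model_parameters(rho_delta = 2))
  expect_gt(w[1], w[2])
  # direction term: with rho_psi = -1 an exact reversal beats straight-ahead
  # by a factor of e (items matched on hue and distance)
  penult <- data.frame(item_id = 4, hue = 24, x = -1, y = 0)
  items3 <- data.frame(item_id = 1:2, hue = c(24, 24),
                       x = c(1, -1), y = c(0, 0))
  st3 <- choice_state(items3, mu = 24, prev = prev, penult = penult)
  w3 <- selection_weights(st3, model_parameters(rho_psi = -1))
  expect_equal(w3[2] / w3[1], exp(1), tolerance = 1e-12)
})

test_that("selection probabilities normalize and validate", {
  expect_equal(selection_probabilities(rep(2, 4)), rep(0.25, 4))
  expect_equal(selection_probabilities(c(1, exp(1))),
               c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))))
  set.seed(1)
  w <- runif(17)
  expect_equal(sum(selection_probabilities(w)), 1, tolerance = 1e-12)
  expect_error(selection_probabilities(c(1, -1)), "positive")
  expect_error(selection_probabilities(numeric(0)), "empty")
})

test_that("trial log-likelihood matches the uniform null and the brute-force oracle", {
  disp <- toy_display()
  p0 <- model_parameters()
  expect_equal(trial_log_likelihood(disp, c(1, 3, 2), p0), -log(24))
  expect_equal(trial_log_likelihood(disp, 2, p0), -log(4))
  pars <- model_parameters(0.1, 0.2, 10, -0.5)
  for (seq in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    expect_equal(trial_log_likelihood(disp, seq, pars),
                 brute_force_trial_loglik(disp, seq, pars),
                 tolerance = 1e-9)
  }
  expect_error(trial_log_likelihood(disp, c(1, 1, 2), p0), "twice")
  expect_error(trial_log_likelihood(disp, c(1, 9), p0), "absent")
})

test_that("complete-ordering probabilities conserve to one", {
  disp <- toy_display()
  pars <- model_parameters(0.15, 0.1, 3, -0.4)
  orders <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  orders <- orders[apply(orders, 1, function(r) length(unique(r)) == 4), ]
  total <- sum(apply(orders, 1, function(r)
    exp(trial_log_likelihood(disp, as.integer(r), pars))))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("raising the proximity coefficient favours the nearest item", {
  items <- data.frame(item_id = 1:3, hue = c(24, 24, 24),
                      x = c(0.1, 0.4, 0.9), y = c(0, 0, 0))
  prev <- data.frame(item_id = 9, hue = 24, x = 0, y = 0)
  st <- choice_state(items, mu = 24, prev = prev)
  probs <- sapply(c(0, 1, 5, 12), function(rd)
    selection_probabilities(selection_weights(st, model_parameters(rho_delta = rd)))[1])
  expect_true(all(diff(probs) > 0))
})

test_that("pointwise log-likelihood is additive over a trial's events", {
  dat <- tiny_dataset()
  truths <- attr(dat, "participant_params")
  pw <- pointwise_log_likelihood(dat, truths)
  tr <- dat$trials[1, ]
  disp <- hueforage:::extract_display(dat, tr$participant, tr$trial)
  sel <- dat$selections[dat$selections$participant == tr$participant &
                          dat$selections$trial == tr$trial, ]
  prow <- truths[truths$participant == tr$participant, ]
  pars <- model_parameters(prow$rho_c, prow$rho_s, prow$rho_delta, prow$rho_psi)
  expect_equal(sum(pw$log_lik[pw$participant == tr$participant &
                                pw$trial == tr$trial]),
               trial_log_likelihood(disp, sel, pars), tolerance = 1e-10)
  # under the zero model, click j has probability 1 / (n remaining)
  pw0 <- pointwise_log_likelihood(dat, model_parameters())
  one <- pw0[pw0$participant == 1 & pw0$trial == 1, ]
  expect_equal(one$log_lik, -log(60 - (one$click_index - 1)))
})

test_that("the flattened event data reproduce the replay likelihood", {
  dat <- tiny_dataset()
  post <- build_log_posterior(dat, "FULL")
  truths <- attr(dat, "participant_params")
  theta <- t(as.matrix(truths[, c("rho_c", "rho_s", "rho_delta", "rho_psi")]))
  ev <- post$events
  ll_cpp <- post$loglik_theta(theta)
  pw <- pointwise_log_likelihood(dat, truths)
  expect_equal(ll_cpp, sum(pw$log_lik), tolerance = 1e-8)
})
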