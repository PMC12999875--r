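variant_names <- c("rho_c", "rho_s", "rho_delta", "rho_psi")

test_that("analytic gradients agree with central differences", {
  dat <- tiny_dataset()
  for (par in c("noncentered", "centered")) {
    post <- build_log_posterior(dat, "FULL", parameterization = par)
    set.seed(13)
    q <- post$init()
    lg <- post$lp_grad(q)
    num <- numeric_gradient(function(qq) post$lp_grad(qq)$lp, q)
    expect_lt(max(abs(num - lg$grad) / (abs(num) + 1)), 1e-4)
  }
  # nested variant with a 3-parameter block
  post3 <- build_log_posterior(dat, "SPATIAL_SWITCH")
  set.seed(14)
  q <- post3$init()
  lg <- post3$lp_grad(q)
  num <- numeric_gradient(function(qq) post3$lp_grad(qq)$lp, q)
  expect_lt(max(abs(num - lg$grad) / (abs(num) + 1)), 1e-4)
})

test_that("the log posterior equals an independent term-by-term computation", {
  dat <- tiny_dataset()
  pr <- prior_spec()
  post <- build_log_posterior(dat, "FULL", priors = pr)
  set.seed(15)
  q <- post$init()
  con <- post$constrain(q)
  # likelihood by replaying every trial in R
  theta_df <- data.frame(participant = post$participants, t(con$theta))
  names(theta_df)[-1] <- variant_names
  ll <- sum(pointwise_log_likelihood(dat, theta_df)$log_lik)
  K <- post$K; m <- post$m
  y <- q[2 * K + seq_len(m)]
  lp_hand <- ll +
    sum(dnorm(con$beta, pr$loc, pr$scale, log = TRUE)) +
    sum(log(pr$sd_rate) - pr$sd_rate * con$sigma + log(con$sigma)) +
    sum(dnorm(con$z, log = TRUE)) +
    hueforage:::corr_log_prior(y, K, pr$lkj_eta)
  expect_equal(post$lp_grad(q)$lp, unname(lp_hand), tolerance = 1e-8)
})

test_that("nested variants share the likelihood on the common subspace", {
  dat <- tiny_dataset()
  full <- build_log_posterior(dat, "FULL")
  spatial <- build_log_posterior(dat, "SPATIAL")
  sw <- build_log_posterior(dat, "SPATIAL_SWITCH")
  theta2 <- matrix(c(8, -0.4), 2, full$P)  # rho_delta, rho_psi per participant
  theta4 <- rbind(0, 0, theta2)
  theta3 <- rbind(0, theta2)
  expect_equal(full$loglik_theta(theta4), spatial$loglik_theta(theta2),
               tolerance = 1e-10)
  expect_equal(full$loglik_theta(theta4), sw$loglik_theta(theta3),
               tolerance = 1e-10)
})

test_that("the C++ sampler reproduces the reference R implementation exactly", {
  dat <- tiny_dataset()
  post <- build_log_posterior(dat, "FULL")
  ev <- post$events
  pr <- post$priors
  set.seed(42)
  q0 <- post$init()
  set.seed(99)
  rc <- hueforage:::nuts_chain_cpp(
    q0, ev$X, ev$ptr, ev$chosen, ev$part, post$K, post$P,
    pr$loc[post$pars], pr$scale[post$pars], pr$sd_rate, pr$lkj_eta,
    TRUE, ev$const_ll_total, 60L, 40L, 10L, 9L, 0.8, 75L, 150L, 25L, 1000,
    FALSE, FALSE)
  set.seed(99)
  rr <- hueforage:::nuts_chain(post$lp_grad, q0, 60, 40)
  expect_equal(rc$draws, rr$draws)
  expect_equal(rc$stepsize, rr$stepsize)
})

test_that("split r-hat flags separated chains and tolerates constant ones", {
  set.seed(9)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(compute_rhat(good), 1.01)
  bad <- cbind(matrix(rnorm(2000), 1000, 2),
               matrix(rnorm(2000, mean = 10), 1000, 2))
  expect_gt(compute_rhat(bad), 1.1)
  expect_equal(compute_rhat(matrix(5, 100, 2)), 1)
  expect_error(compute_rhat(matrix(rnorm(100), 100, 1)), "2 chains")
})

test_that("hpdi returns the shortest interval with first-window tie-break", {
  h <- hpdi(0:99, 0.5)
  expect_equal(unname(h), c(0, 49))
  expect_equal(unname(hpdi(0:99, 0.999)), c(0, 99))
  set.seed(10)
  x <- rnorm(1e5)
  h97 <- hpdi(x, 0.97)
  et <- quantile(x, c(0.015, 0.985))
  expect_lt(max(abs(h97 - et)), 0.06)
  # the HPDI is never wider than the equal-tailed interval
  expect_lte(diff(h97), diff(et) + 1e-9)
  expect_error(hpdi(x, 1.2), "mass")
  expect_error(hpdi(1, 0.5), "2 samples")
})

test_that("fits expose summaries, participant effects and diagnostics", {
  fit <- tiny_fit()
  sm <- summarize_posterior(fit)
  expect_true(all(c("parameter", "mean", "hpdi97_lower", "rhat", "ess") %in%
                    names(sm)))
  expect_true(all(sm$hpdi53_upper - sm$hpdi53_lower <=
                    sm$hpdi97_upper - sm$hpdi97_lower + 1e-12))
  pe <- participant_effects(fit)
  expect_equal(nrow(pe), 4 * 4)  # 4 participants x 4 parameters
  expect_true(all(pe$hpdi97_lower <= pe$mean & pe$mean <= pe$hpdi97_upper))
  expect_true(all(is.finite(fit$rhat)))
  expect_equal(dim(fit$log_lik),
               c(2 * 200, nrow(fit$events)))
  # constant first-click columns carry -log(60)
  expect_true(all(fit$log_lik[, which(fit$events$first)[1]] == -log(60)))
})

test_that("same seed gives identical fits", {
  dat <- tiny_dataset()
  f1 <- fit_foraging(dat, chains = 2, warmup = 60, draws = 60, seed = 7,
                     rhat_action = "none", compute_loglik = FALSE)
  f2 <- fit_foraging(dat, chains = 2, warmup = 60, draws = 60, seed = 7,
                     rhat_action = "none", compute_loglik = FALSE)
  expect_identical(f1$draws, f2$draws)
})
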