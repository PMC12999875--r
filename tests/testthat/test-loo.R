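test_that("constant pointwise likelihoods give exact elpd with zero se", {
  ll <- matrix(-1.2, 50, 3)  # identical columns, no posterior uncertainty
  res <- psis_loo(ll)
  expect_equal(res$elpd, 3 * -1.2)
  expect_equal(res$se, 0)
  expect_true(all(res$pareto_k == -Inf))
  expect_length(res$flagged, 0)
  # distinct constant columns still contribute their exact values
  ll2 <- matrix(rep(c(-1.2, -0.7, -2.2), each = 50), 50, 3)
  expect_equal(psis_loo(ll2)$pointwise, c(-1.2, -0.7, -2.2))
})

test_that("PSIS-LOO matches exact leave-one-out refits in a conjugate model", {
  # y_i ~ N(mu, 1), mu ~ N(0, 1): all posteriors are closed-form
  set.seed(123)
  n <- 20
  y <- rnorm(n, 0.7, 1)
  post_var <- 1 / (n + 1)
  post_mean <- sum(y) * post_var
  S <- 8000
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  ll <- sapply(y, function(yi) dnorm(yi, mu_draws, 1, log = TRUE))
  res <- psis_loo(ll)
  # oracle: exact LOO predictive density, refitting without each observation
  exact <- sum(sapply(seq_len(n), function(i) {
    v <- 1 / (n - 1 + 1)
    m <- sum(y[-i]) * v
    dnorm(y[i], m, sqrt(1 + v), log = TRUE)
  }))
  expect_lt(abs(res$elpd - exact), 0.1)
  expect_true(all(res$pareto_k < 0.7))
  # permutation invariance of the total
  perm <- sample(n)
  expect_equal(psis_loo(ll[, perm])$elpd, res$elpd, tolerance = 1e-10)
})

test_that("the generalized Pareto fit recovers known shapes", {
  qgp <- function(p, k, sigma) sigma / k * ((1 - p)^(-k) - 1)
  set.seed(31)
  for (k_true in c(0.1, 0.4)) {
    x <- qgp(runif(3000), k_true, 1)
    fit <- hueforage:::gpd_fit(x)
    expect_lt(abs(fit$k - k_true), 0.08)
  }
})

test_that("model comparison anchors the best model at zero", {
  set.seed(77)
  ll_a <- matrix(rnorm(400, -1, 0.1), 100, 4)
  res_a <- psis_loo(ll_a)
  single <- compare_foraging_models(only = res_a)
  expect_equal(single$elpd_diff, 0)
  two <- compare_foraging_models(a = res_a, b = res_a)
  expect_equal(two$elpd_diff, c(0, 0))
  expect_equal(two$se_diff, c(0, 0))
  # a clearly better model ranks first with negative diff for the worse one
  ll_b <- ll_a - 0.5
  res_b <- psis_loo(ll_b)
  cmp <- compare_foraging_models(good = res_a, bad = res_b)
  expect_equal(cmp$model, c("good", "bad"))
  expect_equal(cmp$elpd_diff[1], 0)
  expect_lt(cmp$elpd_diff[2], 0)
  ll_c <- ll_a[, 1:3]
  expect_error(compare_foraging_models(a = res_a, c = psis_loo(ll_c)),
               "different numbers of events")
})
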