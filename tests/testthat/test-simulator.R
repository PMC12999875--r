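test_that("participant parameters follow the group model", {
  g0 <- group_parameters(sigma = rep(0, 4))
  th <- draw_participant_parameters(g0, 5)
  for (p in c("rho_c", "rho_s", "rho_delta", "rho_psi"))
    expect_true(all(th[[p]] == g0$beta[[p]]))
  # Monte Carlo moment checks
  set.seed(21)
  g <- group_parameters()
  th <- draw_participant_parameters(g, 1e4)
  sds <- apply(th[, -1], 2, sd)
  expect_true(all(abs(sds - g$sigma) / g$sigma < 0.03))
  corr <- matrix(0.5, 4, 4); diag(corr) <- 1
  gc <- group_parameters(corr = corr)
  thc <- draw_participant_parameters(gc, 1e4)
  cors <- cor(as.matrix(thc[, -1]))
  expect_true(all(abs(cors[lower.tri(cors)] - 0.5) < 0.03))
  expect_error(group_parameters(corr = matrix(1, 4, 4)), "positive definite")
})

test_that("simulated trials honour the quota and reproduce under a seed", {
  set.seed(31)
  disp <- generate_display(distribution_spec(), session_spec())
  pars <- model_parameters(0.08, 0.15, 12, -0.5)
  sel <- simulate_trial(disp, pars)
  taken <- disp$items$is_target[match(sel$item_id, disp$items$item_id)]
  expect_equal(sum(taken), disp$quota)
  expect_equal(anyDuplicated(sel$item_id), 0L)
  expect_equal(sel$click_index, seq_len(nrow(sel)))
  set.seed(77); s1 <- simulate_trial(disp, pars)
  set.seed(77); s2 <- simulate_trial(disp, pars)
  expect_identical(s1, s2)
})

test_that("strong colour tuning concentrates selections on the designated hue", {
  set.seed(41)
  pars <- model_parameters(rho_c = 3)
  hues <- unlist(lapply(1:100, function(i) {
    disp <- generate_display(distribution_spec(), session_spec())
    sel <- simulate_trial(disp, pars)
    disp$items$hue[match(sel$item_id[-1], disp$items$item_id)]  # drop uniform 1st click
  }))
  tab <- sort(table(hues), decreasing = TRUE)
  expect_equal(names(tab)[1], "24")  # modal selected hue is the centre
})

test_that("simulated experiments have the designed shape and round-trip through CSV", {
  dat <- simulate_experiment(group_parameters(), session_spec(n_trials = 4),
                             n_participants = 3, seed = 5)
  expect_equal(nrow(dat$trials), 3 * 4)
  expect_equal(nrow(dat$items), 3 * 4 * 60)
  expect_true(all(table(dat$trials$participant) == 4))
  td <- file.path(tempdir(), "hueforage-roundtrip")
  write_foraging_data(dat, td)
  back <- read_foraging_data(td)
  expect_equal(back$items$hue, dat$items[order(dat$items$participant,
                                               dat$items$trial,
                                               dat$items$item_id), ]$hue)
  expect_equal(nrow(back$selections), nrow(dat$selections))
  expect_equal(sort(names(back$trials)), sort(names(dat$trials)))
  unlink(td, recursive = TRUE)
})

test_that("a trial warns and stops when targets run out before the quota", {
  disp <- toy_display(hues = c(24, 25, 23, 30, 31),
                      x = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      y = rep(0.5, 5),
                      is_target = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      quota = 4)
  set.seed(61)
  expect_warning(sel <- simulate_trial(disp, model_parameters()), "exhausted")
  expect_lte(nrow(sel), 5)
})
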