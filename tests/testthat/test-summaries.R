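make_handmade_data <- function(rt = NULL) {
  # one participant, one trial, four items selected in id order
  items <- data.frame(participant = 1, trial = 1, item_id = 1:4,
                      hue = c(24, 26, 20, 30),
                      x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                      is_target = c(TRUE, TRUE, TRUE, FALSE))
  trials <- data.frame(participant = 1, trial = 1, half = 1, mu = 24, quota = 3)
  sel <- data.frame(participant = 1, trial = 1, click_index = 1:4, item_id = 1:4)
  if (!is.null(rt)) sel$rt <- rt
  foraging_data(items, trials, sel)
}

test_that("selection-order profile aggregates circular distance from mu", {
  d <- make_handmade_data()
  prof <- selection_order_profile(d)
  expect_equal(prof$click_index, 1:4)
  expect_equal(prof$mean_dist, c(0, 2, 4, 6))
  # a trial selecting only the designated hue gives an all-zero profile
  d0 <- make_handmade_data()
  d0$items$hue <- rep(24, 4)
  expect_true(all(selection_order_profile(d0)$mean_dist == 0))
  # invariant to participant relabeling
  d2 <- make_handmade_data()
  d2$items$participant <- 7
  d2$trials$participant <- 7
  d2$selections$participant <- 7
  expect_equal(selection_order_profile(d2)$mean_dist, prof$mean_dist)
})

test_that("travel distances follow the realized path", {
  d <- make_handmade_data()
  disp <- hueforage:::extract_display(d, 1, 1)
  td <- travel_distances(disp, 1:4)
  expect_length(td, 3)
  expect_equal(td, c(1, 1, 1))  # unit-square corners in order
  expect_equal(td, distance_predictor(c(1, 1, 0), c(0, 1, 1),
                                      c(0, 1, 1), c(0, 0, 1)))
  expect_error(travel_distances(disp, 1), "two clicks")
})

test_that("accuracy is the target share of clicks, pooled click-weighted", {
  d <- make_handmade_data()
  acc <- accuracy(d)
  expect_equal(acc$accuracy[acc$participant == "1"], 3 / 4)
  expect_equal(acc$accuracy[acc$participant == "all"], 3 / 4)
  dat <- tiny_dataset()
  acc2 <- accuracy(dat)
  per <- acc2[acc2$participant != "all" & acc2$half == 1, ]
  pooled <- acc2[acc2$participant == "all" & acc2$half == 1, ]
  expect_equal(pooled$accuracy,
               sum(per$accuracy * per$n_clicks) / sum(per$n_clicks))
  d_all <- make_handmade_data()
  d_all$items$is_target <- TRUE
  expect_true(all(accuracy(d_all)$accuracy == 1))
})

test_that("RT descriptives are computed only when RTs exist", {
  miss <- rt_descriptives(make_handmade_data())
  expect_false(miss$available)
  expect_null(miss$by_click)
  flat <- rt_descriptives(make_handmade_data(rt = rep(0.8, 4)))
  expect_true(flat$available)
  expect_true(all(flat$by_click$mean_rt == 0.8))
  expect_true(all(flat$by_distance$mean_rt == 0.8))
  expect_true(all(flat$by_trial$mean_rt == 0.8))
  expect_equal(flat$by_trial$trial_bin, 1)
  # invariant to row order of the selections
  d <- make_handmade_data(rt = c(0.5, 0.9, 0.7, 1.1))
  d_shuf <- d
  d_shuf$selections <- d$selections[c(3, 1, 4, 2), ]
  a <- rt_descriptives(d)
  b <- rt_descriptives(d_shuf)
  expect_equal(a$by_click$mean_rt, b$by_click$mean_rt)
  expect_equal(a$by_distance$mean_rt, b$by_distance$mean_rt)
})
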