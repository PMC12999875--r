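# join selections with item attributes and trial metadata
joined_selections <- function(data) {
  stopifnot(inherits(data, "foraging_data"))
  s <- merge(data$selections,
             data$items[, c("participant", "trial", "item_id", "hue", "x", "y",
                            "is_target")],
             by = c("participant", "trial", "item_id"), sort = FALSE)
  s <- merge(s, data$trials[, c("participant", "trial", "half", "mu")],
             by = c("participant", "trial"), sort = FALSE)
  s[order(s$participant, s$trial, s$click_index), , drop = FALSE]
}

se_mean <- function(x) stats::sd(x) / sqrt(length(x))

#' Selection-order profile of hue distance from the distribution centre
#'
#' For every click rank, the mean absolute circular hue distance of the
#' selected item from the designated hue, with its standard error, split by
#' experiment half. Under strong colour tuning the profile rises with click
#' rank: sampling without replacement depletes near-centre hues so late
#' selections are forced toward the distribution tails.
#'
#' @param data A `foraging_data` object.
#' @return Data frame: `half`, `click_index`, `mean_dist`, `se`, `n`.
#' @export
selection_order_profile <- function(data) {
  s <- joined_selections(data)
  s$dist <- circular_distance(s$hue, s$mu, data$n_hues)
  agg <- do.call(rbind, lapply(split(s, list(s$half, s$click_index), drop = TRUE),
                               function(g) data.frame(
                                 half = g$half[1], click_index = g$click_index[1],
                                 mean_dist = mean(g$dist),
                                 se = if (nrow(g) > 1) se_mean(g$dist) else NA_real_,
                                 n = nrow(g))))
  agg <- agg[order(agg$half, agg$click_index), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-step travel distances along a selection sequence
#'
#' Euclidean distance (normalized display units) between consecutively
#' selected items; a sequence of `n` clicks yields `n - 1` distances. These
#' equal the proximity predictor evaluated along the realized sequence.
#'
#' @param display A `display` object.
#' @param sequence Item ids in click order, or a data frame with
#'   `click_index` and `item_id`.
#' @return Numeric vector of length `n - 1`.
#' @export
travel_distances <- function(display, sequence) {
  if (is.data.frame(sequence))
    sequence <- sequence$item_id[order(sequence$click_index)]
  if (length(sequence) < 2L)
    stop("need at least two clicks to compute travel distances", call. = FALSE)
  idx <- match(sequence, display$items$item_id)
  if (anyNA(idx)) stop("sequence refers to unknown item ids", call. = FALSE)
  x <- display$items$x[idx]
  y <- display$items$y[idx]
  sqrt(diff(x)^2 + diff(y)^2)
}

#' Selection accuracy (targets over distractors)
#'
#' Proportion of clicks landing on targets, per participant and half, with
#' pooled rows (`participant = "all"`) whose accuracy is the click-weighted
#' mean of the per-participant values.
#'
#' @param data A `foraging_data` object.
#' @return Data frame: `half`, `participant`, `n_clicks`, `accuracy`.
#' @export
accuracy <- function(data) {
  s <- joined_selections(data)
  per <- do.call(rbind, lapply(split(s, list(s$half, s$participant), drop = TRUE),
                               function(g) data.frame(
                                 half = g$half[1],
                                 participant = as.character(g$participant[1]),
                                 n_clicks = nrow(g),
                                 accuracy = mean(g$is_target))))
  pooled <- do.call(rbind, lapply(split(s, s$half), function(g) data.frame(
    half = g$half[1], participant = "all", n_clicks = nrow(g),
    accuracy = mean(g$is_target))))
  out <- rbind(per, pooled)
  out <- out[order(out$half, out$participant != "all", out$participant), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptive response-time profiles
#'
#' Computed only when an `rt` column is present in the selections; response
#' times are carried through the pipeline but never modelled. Returns group
#' means and standard errors by click rank and by travel-distance bin, per
#' half. With no usable RTs a structured "not available" result is returned
#' rather than silent zeros.
#'
#' @param data A `foraging_data` object.
#' @param n_distance_bins Number of equal-width travel-distance bins.
#' @param trial_bin_width Width (in trials) of the trial bins for the
#'   per-trial RT profile.
#' @return A list of class `rt_descriptives` with `available`, `by_click`,
#'   `by_distance`, and `by_trial`.
#' @export
rt_descriptives <- function(data, n_distance_bins = 8, trial_bin_width = 3) {
  s <- joined_selections(data)
  if (!"rt" %in% names(s) || all(is.na(s$rt))) {
    return(structure(list(available = FALSE, by_click = NULL,
                          by_distance = NULL, by_trial = NULL,
                          reason = "no rt column in the selection records"),
                     class = "rt_descriptives"))
  }
  s <- s[!is.na(s$rt), , drop = FALSE]
  by_click <- do.call(rbind, lapply(split(s, list(s$half, s$click_index), drop = TRUE),
                                    function(g) data.frame(
                                      half = g$half[1], click_index = g$click_index[1],
                                      mean_rt = mean(g$rt),
                                      se = if (nrow(g) > 1) se_mean(g$rt) else NA_real_,
                                      n = nrow(g))))
  by_click <- by_click[order(by_click$half, by_click$click_index), , drop = FALSE]
  rownames(by_click) <- NULL
  # travel distance from the previous selection within each trial
  s <- s[order(s$participant, s$trial, s$click_index), , drop = FALSE]
  key <- paste(s$participant, s$trial)
  step <- unlist(lapply(split(seq_len(nrow(s)), key), function(ii) {
    if (length(ii) < 2) return(rep(NA_real_, length(ii)))
    c(NA_real_, sqrt(diff(s$x[ii])^2 + diff(s$y[ii])^2))
  }), use.names = FALSE)
  # split() ordered by key; restore original row order
  ord <- order(order(key))
  s$step <- step[ord]
  sd2 <- s[!is.na(s$step), , drop = FALSE]
  by_distance <- NULL
  if (nrow(sd2) > 0) {
    brks <- seq(0, max(sd2$step) + 1e-9, length.out = n_distance_bins + 1)
    sd2$bin <- cut(sd2$step, brks, include.lowest = TRUE)
    by_distance <- do.call(rbind, lapply(split(sd2, list(sd2$half, sd2$bin), drop = TRUE),
                                         function(g) data.frame(
                                           half = g$half[1], bin = as.character(g$bin[1]),
                                           mid = mean(range(g$step)),
                                           mean_rt = mean(g$rt),
                                           se = if (nrow(g) > 1) se_mean(g$rt) else NA_real_,
                                           n = nrow(g))))
    rownames(by_distance) <- NULL
  }
  s$trial_bin <- (s$trial - 1) %/% trial_bin_width + 1
  by_trial <- do.call(rbind, lapply(split(s, list(s$half, s$trial_bin), drop = TRUE),
                                    function(g) data.frame(
                                      half = g$half[1], trial_bin = g$trial_bin[1],
                                      mean_rt = mean(g$rt),
                                      se = if (nrow(g) > 1) se_mean(g$rt) else NA_real_,
                                      n = nrow(g))))
  by_trial <- by_trial[order(by_trial$half, by_trial$trial_bin), , drop = FALSE]
  rownames(by_trial) <- NULL
  structure(list(available = TRUE, by_click = by_click,
                 by_distance = by_distance, by_trial = by_trial),
            class = "rt_descriptives")
}

#' @export
print.rt_descriptives <- function(x, ...) {
  if (!x$available) {
    cat("RT descriptives: not available (", x$reason, ")\n", sep = "")
  } else {
    cat("RT by click rank:\n"); print(utils::head(x$by_click, 10))
    cat("RT by travel-distance bin:\n"); print(x$by_distance)
  }
  invisible(x)
}
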