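#' Model parameters for the sequential choice model
#'
#' The four bias coefficients of the selection-weight model. Selection weights
#' for the remaining items at click \eqn{j \ge 3} are
#' \deqn{w(i) = \exp\{-\rho_c C(i) - \rho_s S(i, j-1)
#'   - \rho_\delta \delta(i, j-1) - \rho_\psi \psi(i, j-1, j-2)\},}
#' where \eqn{C} is the circular hue distance of item \eqn{i} from the
#' designated (distribution-mean) hue, \eqn{S} the hue distance from the
#' previously selected item, \eqn{\delta} the Euclidean distance from the
#' previous item in normalized display units, and \eqn{\psi \in [0,1]} the
#' relative change in travel direction. The second click omits the
#' \eqn{\psi} term (no penultimate selection exists) and the first click is
#' uniform over all items.
#'
#' @param rho_c Colour-tuning coefficient (per JND); positive values favour
#'   hues near the designated centre.
#' @param rho_s Switch coefficient (per JND); positive values favour hues near
#'   the previously selected item's hue.
#' @param rho_delta Proximity coefficient (per normalized distance unit);
#'   positive values favour nearby items.
#' @param rho_psi Direction coefficient; negative values favour reversing the
#'   direction of travel.
#' @return An object of class `model_parameters` (named numeric vector).
#' @export
model_parameters <- function(rho_c = 0, rho_s = 0, rho_delta = 0, rho_psi = 0) {
  p <- c(rho_c = rho_c, rho_s = rho_s, rho_delta = rho_delta, rho_psi = rho_psi)
  if (any(!is.finite(p))) stop("model parameters must be finite", call. = FALSE)
  structure(p, class = c("model_parameters", "numeric"))
}

param_names <- function() c("rho_c", "rho_s", "rho_delta", "rho_psi")

#' Colour predictor: hue distance from the designated centre
#'
#' @param hue Hue index (or vector) of candidate items.
#' @param mu Designated hue index for the relevant experiment half.
#' @param n_hues Size of the circular colour space.
#' @return Circular JND distance(s), `>= 0`.
#' @export
colour_predictor <- function(hue, mu, n_hues = 48) {
  circular_distance(hue, mu, n_hues)
}

#' Switch predictor: hue distance from the previously selected item
#'
#' @param hue Hue index (or vector) of candidate items.
#' @param prev_hue Hue index of the previous selection; must exist (the caller
#'   gates the first click).
#' @inheritParams colour_predictor
#' @return Circular JND distance(s), `>= 0`.
#' @export
switch_predictor <- function(hue, prev_hue, n_hues = 48) {
  if (length(prev_hue) != 1L || is.na(prev_hue))
    stop("switch_predictor requires a single previous selection", call. = FALSE)
  circular_distance(hue, prev_hue, n_hues)
}

#' Proximity predictor: Euclidean distance from the previous selection
#'
#' Positions are in normalized display units, so distances lie in
#' `[0, sqrt(2)]`.
#'
#' @param x,y Candidate item coordinates (vectors).
#' @param prev_x,prev_y Coordinates of the previous selection.
#' @return Euclidean distance(s).
#' @export
distance_predictor <- function(x, y, prev_x, prev_y) {
  sqrt((x - prev_x)^2 + (y - prev_y)^2)
}

#' Direction predictor: relative change in direction of travel
#'
#' Compares the direction from the penultimate to the previous selection with
#' the direction from the previous selection to the candidate. The absolute
#' angular change is scaled to `[0, 1]`: 0 for a candidate directly ahead,
#' 0.5 for a 90-degree turn, 1 for doubling back. A degenerate (zero-length)
#' travel vector yields the uninformative midpoint 0.5.
#'
#' @param x,y Candidate coordinates (vectors).
#' @param prev_x,prev_y Previous selection's coordinates.
#' @param penult_x,penult_y Penultimate selection's coordinates.
#' @return Values in `[0, 1]`.
#' @export
direction_predictor <- function(x, y, prev_x, prev_y, penult_x, penult_y) {
  v1x <- prev_x - penult_x
  v1y <- prev_y - penult_y
  v2x <- x - prev_x
  v2y <- y - prev_y
  dot <- v1x * v2x + v1y * v2y
  crs <- v1x * v2y - v1y * v2x
  psi <- abs(atan2(crs, dot)) / pi
  degenerate <- (v1x == 0 & v1y == 0) | (v2x == 0 & v2y == 0)
  psi[degenerate] <- 0.5
  psi
}

#' Choice state within a trial
#'
#' Snapshot of a single selection opportunity: the remaining items, the mu of
#' the half, and the one or two most recent selections (rows of the original
#' item table, already removed from `remaining`).
#'
#' @param remaining Data frame of remaining items (`hue`, `x`, `y`, and
#'   usually `item_id`).
#' @param mu Designated hue.
#' @param prev,penult Single-row data frames (or `NULL`) for the last and
#'   second-to-last selections.
#' @param n_hues Colour-space size.
#' @return An object of class `choice_state`.
#' @export
choice_state <- function(remaining, mu, prev = NULL, penult = NULL, n_hues = 48) {
  if (nrow(remaining) == 0L) stop("remaining item set is empty", call. = FALSE)
  if (is.null(prev) && !is.null(penult))
    stop("cannot have a penultimate selection without a previous one", call. = FALSE)
  structure(list(remaining = remaining, mu = mu, prev = prev,
                 penult = penult, n_hues = n_hues),
            class = "choice_state")
}

#' Selection weights over the remaining items
#'
#' Evaluates the exponential-bias weight for every remaining item, in log
#' space for stability; returned weights are scaled so the largest is 1 (only
#' weight ratios are meaningful — [selection_probabilities()] normalizes).
#' The first click returns uniform weights; the second click omits the
#' direction term.
#'
#' @param state A [choice_state()].
#' @param params A [model_parameters()] (or named numeric vector with entries
#'   `rho_c`, `rho_s`, `rho_delta`, `rho_psi`).
#' @return Positive numeric vector, one weight per remaining item.
#' @export
selection_weights <- function(state, params) {
  stopifnot(inherits(state, "choice_state"))
  r <- state$remaining
  if (is.null(state$prev)) return(rep(1, nrow(r)))
  lw <- -params[["rho_c"]] * colour_predictor(r$hue, state$mu, state$n_hues) -
    params[["rho_s"]] * switch_predictor(r$hue, state$prev$hue, state$n_hues) -
    params[["rho_delta"]] * distance_predictor(r$x, r$y, state$prev$x, state$prev$y)
  if (!is.null(state$penult)) {
    lw <- lw - params[["rho_psi"]] *
      direction_predictor(r$x, r$y, state$prev$x, state$prev$y,
                          state$penult$x, state$penult$y)
  }
  exp(lw - max(lw))
}

#' Normalize weights to choice probabilities
#'
#' @param weights Positive, finite weights.
#' @return Probability vector summing to 1.
#' @export
selection_probabilities <- function(weights) {
  if (length(weights) == 0L) stop("empty weight vector", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  weights / sum(weights)
}

#' Log-likelihood of an observed selection sequence
#'
#' Replays the trial: the candidate set at every click contains all remaining
#' items, targets and distractors alike; the selected item (of either kind) is
#' removed. The first click contributes `-log(n_items)` (uniform over the full
#' display, equivalent to choosing a hue with probability proportional to its
#' onscreen frequency); later clicks contribute the log choice probability
#' under the bias model.
#'
#' @param display A `display` (see [generate_display()]) or any list with an
#'   `items` data frame, `mu`, and `n_hues`.
#' @param sequence Integer vector of selected `item_id`s in click order, or a
#'   data frame with columns `click_index` and `item_id`.
#' @param params A [model_parameters()].
#' @param pointwise If `TRUE`, return the vector of per-click log
#'   probabilities instead of their sum.
#' @return Log probability of the sequence (or per-click vector).
#' @export
trial_log_likelihood <- function(display, sequence, params, pointwise = FALSE) {
  items <- display$items
  if (is.data.frame(sequence)) {
    sequence <- sequence$item_id[order(sequence$click_index)]
  }
  idx <- match(sequence, items$item_id)
  if (anyNA(idx))
    stop("selection sequence refers to item ids absent from the display", call. = FALSE)
  if (anyDuplicated(sequence))
    stop("an item was selected twice; sampling is without replacement", call. = FALSE)
  remaining <- seq_len(nrow(items))
  prev <- NULL
  penult <- NULL
  ll <- numeric(length(idx))
  for (j in seq_along(idx)) {
    pos <- match(idx[j], remaining)
    if (is.na(pos)) stop("selected item no longer in the remaining set", call. = FALSE)
    st <- choice_state(items[remaining, , drop = FALSE], display$mu,
                       prev = prev, penult = penult, n_hues = display$n_hues)
    w <- selection_weights(st, params)
    ll[j] <- log(w[pos]) - log(sum(w))
    penult <- prev
    prev <- items[remaining[pos], , drop = FALSE]
    remaining <- remaining[-pos]
  }
  if (pointwise) ll else sum(ll)
}

#' Pointwise log-likelihood for a dataset
#'
#' One log probability per selection event (click), treating each selection
#' instance as a separate observation. Within a trial the entries sum to
#' [trial_log_likelihood()].
#'
#' @param data A `foraging_data` object (see [foraging_data()]).
#' @param participant_params A data frame with columns `participant`,
#'   `rho_c`, `rho_s`, `rho_delta`, `rho_psi`, one row per participant, or a
#'   single [model_parameters()] applied to everyone.
#' @return Data frame with `participant`, `trial`, `click_index`, `log_lik`.
#' @export
pointwise_log_likelihood <- function(data, participant_params) {
  stopifnot(inherits(data, "foraging_data"))
  if (inherits(participant_params, "model_parameters") ||
      (is.numeric(participant_params) && !is.null(names(participant_params)))) {
    participant_params <- data.frame(
      participant = unique(data$trials$participant),
      rho_c = participant_params[["rho_c"]], rho_s = participant_params[["rho_s"]],
      rho_delta = participant_params[["rho_delta"]], rho_psi = participant_params[["rho_psi"]]
    )
  }
  out <- vector("list", nrow(data$trials))
  for (k in seq_len(nrow(data$trials))) {
    tr <- data$trials[k, ]
    prow <- participant_params[participant_params$participant == tr$participant, ]
    if (nrow(prow) != 1L)
      stop(sprintf("no parameters supplied for participant %s", tr$participant),
           call. = FALSE)
    pars <- model_parameters(prow$rho_c, prow$rho_s, prow$rho_delta, prow$rho_psi)
    disp <- extract_display(data, tr$participant, tr$trial)
    sel <- data$selections[data$selections$participant == tr$participant &
                             data$selections$trial == tr$trial, ]
    if (nrow(sel) == 0L) next
    ll <- trial_log_likelihood(disp, sel, pars, pointwise = TRUE)
    out[[k]] <- data.frame(participant = tr$participant, trial = tr$trial,
                           click_index = sort(sel$click_index), log_lik = ll)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
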