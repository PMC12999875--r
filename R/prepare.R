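# Flatten a dataset into the event structure consumed by the likelihood
# kernel. Events are in canonical order (participant, trial, click_index).
# First clicks are uniform over the full display and enter only as constants;
# all later clicks get one predictor row per remaining candidate item.
# Second clicks carry a zero direction column (the psi term is omitted when
# no penultimate selection exists), which is exact because the weight then
# reduces to the three-term form.

variant_params <- function(variant) {
  switch(variant,
         FULL = c("rho_c", "rho_s", "rho_delta", "rho_psi"),
         SPATIAL_SWITCH = c("rho_s", "rho_delta", "rho_psi"),
         SPATIAL = c("rho_delta", "rho_psi"),
         stop(sprintf("unknown model variant '%s'", variant), call. = FALSE))
}

prepare_event_data <- function(data, variant = "FULL", half = "all") {
  stopifnot(inherits(data, "foraging_data"))
  half <- match.arg(half, c("all", "first", "second"))
  pars <- variant_params(variant)
  trials <- data$trials
  if (half == "first") trials <- trials[trials$half == 1, , drop = FALSE]
  if (half == "second") trials <- trials[trials$half == 2, , drop = FALSE]
  if (nrow(trials) == 0L) stop("no trials in the requested half", call. = FALSE)
  trials <- trials[order(trials$participant, trials$trial), , drop = FALSE]
  participants <- sort(unique(trials$participant))

  ikey <- paste(data$items$participant, data$items$trial)
  skey <- paste(data$selections$participant, data$selections$trial)

  Xl <- list()
  sizes <- integer(0)     # candidates per non-first event
  chosen <- integer(0)    # 0-based within event
  part <- integer(0)      # 0-based participant per non-first event
  ev_participant <- c(); ev_trial <- c(); ev_click <- c(); ev_first <- logical(0)
  ev_const <- numeric(0)  # first-click constant log-lik (NA otherwise)
  n_hues <- data$n_hues

  for (r in seq_len(nrow(trials))) {
    tr <- trials[r, ]
    it <- data$items[ikey == paste(tr$participant, tr$trial), , drop = FALSE]
    sel <- data$selections[skey == paste(tr$participant, tr$trial), , drop = FALSE]
    if (nrow(sel) == 0L) next
    sel <- sel[order(sel$click_index), , drop = FALSE]
    idx <- match(sel$item_id, it$item_id)
    if (anyNA(idx))
      stop(sprintf("trial %s/%s: selection of unknown item", tr$participant, tr$trial),
           call. = FALSE)
    hue <- it$hue; xx <- it$x; yy <- it$y
    n <- nrow(it)
    rem <- seq_len(n)
    pidx <- match(tr$participant, participants) - 1L
    prev <- NA_integer_; penult <- NA_integer_
    for (j in seq_along(idx)) {
      pos <- match(idx[j], rem)
      if (is.na(pos))
        stop(sprintf("trial %s/%s: item selected twice", tr$participant, tr$trial),
             call. = FALSE)
      ev_participant <- c(ev_participant, tr$participant)
      ev_trial <- c(ev_trial, tr$trial)
      ev_click <- c(ev_click, sel$click_index[j])
      if (j == 1L) {
        ev_first <- c(ev_first, TRUE)
        ev_const <- c(ev_const, -log(n))
      } else {
        ev_first <- c(ev_first, FALSE)
        ev_const <- c(ev_const, NA_real_)
        rh <- hue[rem]
        M <- cbind(
          rho_c = circular_distance(rh, tr$mu, n_hues),
          rho_s = circular_distance(rh, hue[prev], n_hues),
          rho_delta = sqrt((xx[rem] - xx[prev])^2 + (yy[rem] - yy[prev])^2),
          rho_psi = if (j >= 3L)
            direction_predictor(xx[rem], yy[rem], xx[prev], yy[prev],
                                xx[penult], yy[penult])
          else rep(0, length(rem))
        )
        Xl[[length(Xl) + 1L]] <- M[, pars, drop = FALSE]
        sizes <- c(sizes, length(rem))
        chosen <- c(chosen, pos - 1L)
        part <- c(part, pidx)
      }
      penult <- prev
      prev <- rem[pos]
      rem <- rem[-pos]
    }
  }
  X <- do.call(rbind, Xl)
  if (is.null(X)) X <- matrix(numeric(0), 0, length(pars), dimnames = list(NULL, pars))
  # candidate-major layout (K x N): one candidate's predictors are contiguous
  X <- t(X)
  ptr <- c(0L, cumsum(sizes))
  events <- data.frame(participant = ev_participant, trial = ev_trial,
                       click_index = ev_click, first = ev_first,
                       const_ll = ev_const)
  list(X = X, ptr = as.integer(ptr), chosen = as.integer(chosen),
       part = as.integer(part), events = events,
       participants = participants, pars = pars,
       const_ll_total = sum(ev_const, na.rm = TRUE))
}
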