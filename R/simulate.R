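#' Group-level parameters of the multilevel model
#'
#' Participant-specific parameter vectors are generated as
#' \eqn{\theta_p = \beta + \mathrm{diag}(\sigma) L z_p}, with \eqn{L} the
#' lower Cholesky factor of the correlation matrix and \eqn{z_p} iid standard
#' normal. The defaults are the package's ground-truth fixture for recovery
#' studies: mean-seeking and switch-averse in colour space, strongly
#' proximity-biased, mildly reversal-preferring.
#'
#' @param beta Length-4 fixed effects `(rho_c, rho_s, rho_delta, rho_psi)`.
#' @param sigma Length-4 nonnegative random-effect SDs.
#' @param corr 4 x 4 correlation matrix (symmetric positive definite, unit
#'   diagonal).
#' @return An object of class `group_parameters`.
#' @export
group_parameters <- function(beta = c(rho_c = 0.08, rho_s = 0.15,
                                      rho_delta = 12, rho_psi = -0.5),
                             sigma = c(0.03, 0.05, 3, 0.3),
                             corr = diag(4)) {
  stopifnot(length(beta) == 4, length(sigma) == 4, all(sigma >= 0),
            is.matrix(corr), all(dim(corr) == c(4, 4)))
  if (max(abs(corr - t(corr))) > 1e-12 || max(abs(diag(corr) - 1)) > 1e-12)
    stop("`corr` must be symmetric with unit diagonal", call. = FALSE)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("`corr` must be positive definite", call. = FALSE)
  names(beta) <- names(sigma) <- param_names()
  structure(list(beta = beta, sigma = sigma, corr = corr),
            class = "group_parameters")
}

#' Draw participant-specific parameters from the group model
#'
#' @param group A [group_parameters()].
#' @param n Number of participants.
#' @return Data frame with columns `participant`, `rho_c`, `rho_s`,
#'   `rho_delta`, `rho_psi`.
#' @export
draw_participant_parameters <- function(group, n) {
  stopifnot(inherits(group, "group_parameters"), n >= 1)
  L <- t(chol(group$corr))
  z <- matrix(stats::rnorm(4 * n), 4, n)
  theta <- group$beta + group$sigma * (L %*% z)  # 4 x n
  out <- as.data.frame(t(theta))
  names(out) <- param_names()
  cbind(participant = seq_len(n), out)
}

#' Simulate one foraging trial
#'
#' Iteratively evaluates the choice probabilities over the remaining items
#' (targets and distractors alike), samples the next selection, and removes
#' it. The trial ends when `quota` targets have been selected; distractor
#' clicks remove the distractor but do not advance the quota. If targets run
#' out before the quota is met a warning is raised and the trial ends.
#'
#' @param display A `display` (see [generate_display()]).
#' @param params A [model_parameters()].
#' @return Data frame with columns `click_index` and `item_id`.
#' @export
simulate_trial <- function(display, params) {
  items <- display$items
  remaining <- seq_len(nrow(items))
  prev <- NULL
  penult <- NULL
  targets_taken <- 0L
  picks <- integer(0)
  while (targets_taken < display$quota && length(remaining) > 0L) {
    st <- choice_state(items[remaining, , drop = FALSE], display$mu,
                       prev = prev, penult = penult, n_hues = display$n_hues)
    p <- selection_probabilities(selection_weights(st, params))
    pos <- sample.int(length(remaining), 1L, prob = p)
    sel <- remaining[pos]
    picks <- c(picks, items$item_id[sel])
    if (items$is_target[sel]) targets_taken <- targets_taken + 1L
    penult <- prev
    prev <- items[sel, , drop = FALSE]
    remaining <- remaining[-pos]
    if (targets_taken < display$quota && !any(items$is_target[remaining])) {
      warning("targets exhausted before the quota was met; ending trial",
              call. = FALSE)
      break
    }
  }
  data.frame(click_index = seq_along(picks), item_id = picks)
}

#' Simulate a full multi-participant experiment
#'
#' For each participant: draw parameters from the group model once, generate a
#' fresh session of displays, and simulate every trial. The result is a
#' canonical [foraging_data()] object (round-trippable through
#' [write_foraging_data()] / [read_foraging_data()]).
#'
#' @param group A [group_parameters()].
#' @param session A [session_spec()].
#' @param n_participants Number of simulated observers.
#' @param seed Optional integer seed; if supplied, the simulation is a pure
#'   function of `(group, session, n_participants, seed)`.
#' @return A `foraging_data` object with an attached attribute
#'   `participant_params` (the drawn truths, useful for recovery studies).
#' @export
simulate_experiment <- function(group = group_parameters(),
                                session = session_spec(),
                                n_participants = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truths <- draw_participant_parameters(group, n_participants)
  items_l <- list(); trials_l <- list(); sel_l <- list()
  for (p in seq_len(n_participants)) {
    pars <- model_parameters(truths$rho_c[p], truths$rho_s[p],
                             truths$rho_delta[p], truths$rho_psi[p])
    sess <- generate_session(session)
    for (tr in sess) {
      d <- tr$display
      sel <- suppressWarnings(simulate_trial(d, pars))
      items_l[[length(items_l) + 1L]] <-
        cbind(participant = p, trial = tr$trial, d$items)
      trials_l[[length(trials_l) + 1L]] <-
        data.frame(participant = p, trial = tr$trial, half = tr$half,
                   mu = d$mu, quota = d$quota)
      sel_l[[length(sel_l) + 1L]] <-
        cbind(participant = p, trial = tr$trial, sel)
    }
  }
  out <- foraging_data(do.call(rbind, items_l), do.call(rbind, trials_l),
                       do.call(rbind, sel_l), n_hues = session$dist$n_hues)
  attr(out, "participant_params") <- truths
  attr(out, "group_parameters") <- group
  out
}
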