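#' Parameter-recovery harness
#'
#' End-to-end check of the simulate-then-fit loop: for each seed, simulate an
#' experiment from known group parameters, fit the model, and record for every
#' fixed effect whether the posterior mean has the true sign and whether the
#' 97% HPDI covers the truth, along with the convergence diagnostics. The
#' default scale (8 participants, 12 trials, 2 chains of 500 + 500) is the
#' package's scaled-down recovery benchmark.
#'
#' @param truth A [group_parameters()] generating the data.
#' @param n_participants,n_trials Simulation scale per seed.
#' @param seeds Integer vector of seeds (one simulated experiment + fit each).
#' @param variant Model variant to fit.
#' @param chains,warmup,draws Sampler size per fit.
#' @param session Optional [session_spec()]; defaults to `n_trials` trials
#'   with no mid-session distribution shift, so all trials share one
#'   distribution and are fitted jointly.
#' @param control Sampler control list passed to [fit_foraging()].
#' @return An object of class `recovery_report`: list with `per_seed` (one
#'   row per seed x parameter), `aggregate` (per-parameter sign and coverage
#'   rates), and `truth`.
#' @export
recover_parameters <- function(truth = group_parameters(),
                               n_participants = 8, n_trials = 12,
                               seeds = 1:5, variant = "FULL",
                               chains = 2, warmup = 500, draws = 500,
                               session = NULL, control = list()) {
  if (is.null(session))
    session <- session_spec(n_trials = n_trials, shift = 0)
  pars <- variant_params(variant)
  beta_true <- truth$beta[pars]
  rows <- list()
  for (sd in seeds) {
    data <- simulate_experiment(truth, session, n_participants, seed = sd)
    fit <- fit_foraging(data, variant = variant, chains = chains,
                        warmup = warmup, draws = draws, seed = sd,
                        compute_loglik = FALSE, control = control,
                        rhat_action = "none")
    max_rhat <- max(fit$rhat, na.rm = TRUE)
    for (p in pars) {
      x <- as.numeric(fit$draws[, , paste0("beta[", p, "]")])
      h <- hpdi(x, 0.97)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd, parameter = p, truth = beta_true[[p]],
        post_mean = mean(x), hpdi97_lower = h[[1]], hpdi97_upper = h[[2]],
        sign_ok = sign(mean(x)) == sign(beta_true[[p]]),
        covered = beta_true[[p]] >= h[[1]] && beta_true[[p]] <= h[[2]],
        max_rhat = max_rhat, divergences = fit$divergences,
        converged = max_rhat < 1.01)
    }
  }
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  aggregate <- do.call(rbind, lapply(split(per_seed, per_seed$parameter),
                                     function(g) data.frame(
                                       parameter = g$parameter[1],
                                       truth = g$truth[1],
                                       sign_rate = mean(g$sign_ok),
                                       coverage = mean(g$covered),
                                       mean_abs_error = mean(abs(g$post_mean - g$truth)))))
  rownames(aggregate) <- NULL
  structure(list(per_seed = per_seed, aggregate = aggregate, truth = truth,
                 n_participants = n_participants, n_trials = n_trials,
                 seeds = seeds, variant = variant),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s model, %d participants x %d trials, seeds: %s\n",
              x$variant, x$n_participants, x$n_trials,
              paste(x$seeds, collapse = ", ")))
  print(x$aggregate, digits = 3)
  nc <- x$per_seed[!x$per_seed$converged, "seed"]
  if (length(nc)) cat("non-converged seeds:", paste(unique(nc), collapse = ", "), "\n")
  invisible(x)
}
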