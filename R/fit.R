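#' Fit the multilevel foraging model by NUTS
#'
#' Samples the posterior of the hierarchical sequential-choice model with the
#' package's built-in No-U-Turn sampler. Random effects use the non-centered
#' parameterization; the stored draws include the fixed effects, group SDs,
#' random-effect correlations and the derived participant coefficients.
#' Convergence is checked with split-chain r-hat; by default the fit fails
#' loudly if any r-hat is 1.01 or larger.
#'
#' @param data A `foraging_data` object.
#' @param variant `"FULL"`, `"SPATIAL_SWITCH"`, or `"SPATIAL"`.
#' @param priors A [prior_spec()].
#' @param chains Number of MCMC chains (at least 2 for diagnostics).
#' @param warmup,draws Warmup and post-warmup iterations per chain.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`. Two fits with the
#'   same seed produce identical draws.
#' @param half Fit `"all"` trials or a single experiment half.
#' @param likelihood If `FALSE`, sample from the priors only.
#' @param compute_loglik Store the per-event pointwise log-likelihood matrix
#'   (needed for [psis_loo()]).
#' @param parameterization Random-effect parameterization: `"noncentered"`
#'   (default; robust when group-level SDs are weakly identified) or
#'   `"centered"`.
#' @param control Sampler control list (`max_treedepth`, `adapt_delta`,
#'   `metric` = "diag"/"dense", buffer sizes, ...).
#' @param rhat_action What to do when max r-hat >= 1.01: `"error"`, `"warn"`,
#'   or `"none"`.
#' @return An object of class `foraging_fit`.
#' @export
fit_foraging <- function(data, variant = "FULL", priors = prior_spec(),
                         chains = 4, warmup = 1000, draws = 1000,
                         seed = NULL, half = "all", likelihood = TRUE,
                         compute_loglik = likelihood,
                         parameterization = c("noncentered", "centered"),
                         control = list(),
                         rhat_action = c("error", "warn", "none")) {
  rhat_action <- match.arg(rhat_action)
  parameterization <- match.arg(parameterization)
  stopifnot(chains >= 2, warmup >= 50, draws >= 50)
  post <- build_log_posterior(data, variant = variant, priors = priors,
                              half = half, likelihood = likelihood,
                              parameterization = parameterization)
  ctl <- utils::modifyList(list(max_treedepth = 10, warmup_treedepth = 9,
                                adapt_delta = 0.8,
                                init_buffer = 75, term_buffer = 150,
                                base_window = 25, max_delta_energy = 1000,
                                metric = "diag"),
                           control)
  ev <- post$events
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1L)
    q0 <- post$init()
    runs[[ch]] <- nuts_chain_cpp(
      q0, ev$X, ev$ptr, ev$chosen, ev$part, post$K, post$P,
      priors$loc[post$pars], priors$scale[post$pars], priors$sd_rate,
      priors$lkj_eta, likelihood, ev$const_ll_total,
      as.integer(warmup), as.integer(draws),
      as.integer(ctl$max_treedepth), as.integer(ctl$warmup_treedepth),
      ctl$adapt_delta,
      as.integer(ctl$init_buffer), as.integer(ctl$term_buffer),
      as.integer(ctl$base_window), ctl$max_delta_energy,
      identical(ctl$metric, "dense"),
      parameterization == "centered")
  }

  K <- post$K; P <- post$P; m <- post$m
  par_names <- c(paste0("beta[", post$pars, "]"),
                 paste0("sigma[", post$pars, "]"),
                 post$corr_names,
                 paste0("theta[", rep(post$participants, each = K), ",",
                        rep(post$pars, P), "]"))
  n_par <- length(par_names)
  arr <- array(NA_real_, c(draws, chains, n_par),
               dimnames = list(NULL, NULL, par_names))
  theta_draws <- array(NA_real_, c(K, P, draws * chains))
  s <- 0L
  for (ch in seq_len(chains)) {
    for (i in seq_len(draws)) {
      s <- s + 1L
      con <- post$constrain(runs[[ch]]$draws[i, ])
      corr_vals <- if (m > 0) con$corr[lower.tri(con$corr)] else numeric(0)
      arr[i, ch, ] <- c(con$beta, con$sigma, corr_vals, as.numeric(con$theta))
      theta_draws[, , s] <- con$theta
    }
  }

  rhat <- compute_rhat(arr)
  ess <- apply(arr, 3, function(x) ess_one(x))
  mcse <- apply(arr, 3, stats::sd) / sqrt(pmax(ess, 1))
  divergences <- sum(vapply(runs, `[[`, 0L, "divergences"))
  lp_mat <- vapply(runs, `[[`, numeric(draws), "lp")
  if (is.null(dim(lp_mat))) lp_mat <- matrix(lp_mat, nrow = draws)

  log_lik <- NULL
  events <- post$events$events
  if (compute_loglik && likelihood) {
    nev <- nrow(events)
    log_lik <- matrix(NA_real_, draws * chains, nev)
    first <- events$first
    ll_model <- cf_event_ll_draws(post$events$X, post$events$ptr,
                                  post$events$chosen, post$events$part,
                                  as.numeric(theta_draws), K, P, draws * chains)
    log_lik[, !first] <- ll_model
    if (any(first))
      log_lik[, first] <- matrix(rep(events$const_ll[first], each = draws * chains),
                                 nrow = draws * chains)
  }

  fit <- structure(
    list(draws = arr, lp = lp_mat, posterior = post,
         rhat = rhat, ess = ess, mcse = mcse,
         divergences = divergences,
         stepsize = vapply(runs, `[[`, 0, "stepsize"),
         accept_rate = vapply(runs, `[[`, 0, "accept_rate"),
         log_lik = log_lik, events = events,
         variant = variant, half = half, likelihood = likelihood,
         meta = list(chains = chains, warmup = warmup, draws = draws,
                     seed = seed)),
    class = "foraging_fit"
  )

  max_rhat <- max(rhat, na.rm = TRUE)
  if (max_rhat >= 1.01 && rhat_action != "none") {
    worst <- names(which.max(rhat))
    msg <- sprintf(
      "convergence check failed: max r-hat = %.4f (%s) >= 1.01 across %d parameters; %d divergent transitions",
      max_rhat, worst, n_par, divergences)
    if (rhat_action == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  fit
}

#' @export
print.foraging_fit <- function(x, ...) {
  cat(sprintf("<foraging_fit> variant %s, %d chains x %d draws (warmup %d)\n",
              x$variant, x$meta$chains, x$meta$draws, x$meta$warmup))
  cat(sprintf("  max r-hat %.4f | divergences %d | mean accept %.2f\n",
              max(x$rhat, na.rm = TRUE), x$divergences, mean(x$accept_rate)))
  fe <- summarize_posterior(x, pars = paste0("beta[", x$posterior$pars, "]"))
  print(fe, digits = 3)
  invisible(x)
}

# draws for one named parameter as a (iterations x chains) matrix
fit_param_matrix <- function(fit, par) {
  stopifnot(par %in% dimnames(fit$draws)[[3]])
  fit$draws[, , par]
}

# all draws pooled across chains, one column per parameter
fit_draws_matrix <- function(fit, pars = NULL) {
  d <- fit$draws
  if (is.null(pars)) pars <- dimnames(d)[[3]]
  out <- sapply(pars, function(p) as.numeric(d[, , p]))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(pars),
                                       dimnames = list(NULL, pars))
  out
}

#' Posterior summary table
#'
#' Mean, median and the 53/89/97% highest-density intervals per parameter,
#' together with r-hat and effective sample size.
#'
#' @param fit A `foraging_fit`.
#' @param pars Parameter names to summarise (default: fixed effects, group
#'   SDs and correlations).
#' @return A data frame, one row per parameter.
#' @export
summarize_posterior <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "foraging_fit"))
  all_pars <- dimnames(fit$draws)[[3]]
  if (is.null(pars))
    pars <- all_pars[!startsWith(all_pars, "theta[")]
  bad <- setdiff(pars, all_pars)
  if (length(bad))
    stop(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  rows <- lapply(pars, function(p) {
    x <- as.numeric(fit$draws[, , p])
    h53 <- hpdi(x, 0.53); h89 <- hpdi(x, 0.89); h97 <- hpdi(x, 0.97)
    data.frame(parameter = p, mean = mean(x), median = stats::median(x),
               hpdi53_lower = h53[[1]], hpdi53_upper = h53[[2]],
               hpdi89_lower = h89[[1]], hpdi89_upper = h89[[2]],
               hpdi97_lower = h97[[1]], hpdi97_upper = h97[[2]],
               rhat = fit$rhat[[p]], ess = fit$ess[[p]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Participant-level effect summaries
#'
#' Posterior mean and 97% HPDI of every participant-specific coefficient
#' (one row per participant per model parameter).
#'
#' @param fit A `foraging_fit`.
#' @return A data frame with `participant`, `parameter`, `mean`,
#'   `hpdi97_lower`, `hpdi97_upper`.
#' @export
participant_effects <- function(fit) {
  stopifnot(inherits(fit, "foraging_fit"))
  post <- fit$posterior
  rows <- list()
  for (p in post$participants) {
    for (par in post$pars) {
      nm <- sprintf("theta[%s,%s]", p, par)
      x <- as.numeric(fit$draws[, , nm])
      h <- hpdi(x, 0.97)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, parameter = par, mean = mean(x),
        hpdi97_lower = h[[1]], hpdi97_upper = h[[2]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
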