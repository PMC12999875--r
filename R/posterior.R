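#' Prior specification for the multilevel model
#'
#' Defaults follow the model's published priors: weakly informative normals
#' on the colour and switch fixed effects (SD 0.1), Normal(15, 5) on
#' proximity, Normal(0, 1) on direction; Exponential(rate 5) on the
#' group-level SDs; LKJ(eta) on the random-effect correlation matrix.
#' The second element of each pair is a standard deviation.
#'
#' @param rho_c,rho_s,rho_delta,rho_psi Length-2 `(location, sd)` of the
#'   normal prior on each fixed effect.
#' @param sd_rate Rate of the exponential prior on the group-level SDs.
#' @param lkj_eta Shape of the LKJ prior (`eta = 2` weakly favours identity).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(rho_c = c(0, 0.1), rho_s = c(0, 0.1),
                       rho_delta = c(15, 5), rho_psi = c(0, 1),
                       sd_rate = 5, lkj_eta = 2) {
  fe <- rbind(rho_c = rho_c, rho_s = rho_s, rho_delta = rho_delta,
              rho_psi = rho_psi)
  stopifnot(ncol(fe) == 2, all(fe[, 2] > 0), sd_rate > 0, lkj_eta > 0)
  structure(list(loc = fe[, 1], scale = fe[, 2], sd_rate = sd_rate,
                 lkj_eta = lkj_eta), class = "prior_spec")
}

# Lower Cholesky factor of a correlation matrix from unconstrained canonical
# partial correlations y (tanh transform), row-filling order.
chol_from_y <- function(y, K) {
  L <- diag(K)
  if (K < 2L) return(L)
  w <- tanh(y)
  idx <- 1L
  for (i in 2:K) {
    s <- 1
    for (j in 1:(i - 1)) {
      L[i, j] <- w[idx] * sqrt(s)
      s <- s - L[i, j]^2
      idx <- idx + 1L
    }
    L[i, i] <- sqrt(s)
  }
  L
}

# LKJ(eta) log kernel on the Cholesky factor plus the log Jacobian of the
# y -> L transform (tanh derivative and the sqrt scale of each entry).
corr_log_prior <- function(y, K, eta) {
  if (K < 2L || length(y) == 0L) return(0)
  w <- tanh(y)
  lp <- sum(log1p(-w^2))
  idx <- 1L
  for (i in 2:K) {
    s <- 1
    for (j in 1:(i - 1)) {
      lp <- lp + 0.5 * log(s)
      Lij <- w[idx] * sqrt(s)
      s <- s - Lij^2
      idx <- idx + 1L
    }
    lp <- lp + (K - i + 2 * eta - 2) * log(sqrt(s))
  }
  lp
}

#' Build the multilevel log posterior
#'
#' Assembles a differentiable log-density object for the sequential-choice
#' model under one of the nested variants. Participant coefficients follow
#' \eqn{\theta_p \sim N(\beta, D L L' D)} with \eqn{D =
#' \mathrm{diag}(\sigma)} and \eqn{L} the Cholesky factor of the
#' LKJ-distributed correlation matrix. Two mathematically equivalent
#' parameterizations are available: `"noncentered"` (default) samples
#' standard-normal \eqn{z_p} with \eqn{\theta_p = \beta + D L z_p},
#' which is robust when the group-level SDs are weakly identified;
#' `"centered"` samples \eqn{\theta_p} directly. The unconstrained vector is
#' `(beta, log sigma, y, theta-or-z)` where `y` are tanh-transformed
#' canonical partial correlations. Gradients of the likelihood, normal, and
#' exponential terms are analytic; the small correlation-transform block is
#' differentiated by central differences.
#'
#' @param data A `foraging_data` object.
#' @param variant `"FULL"` (all four biases), `"SPATIAL_SWITCH"`
#'   (`rho_s`, `rho_delta`, `rho_psi`), or `"SPATIAL"` (`rho_delta`,
#'   `rho_psi`). Excluded coefficients are fixed at zero in the likelihood
#'   and dropped from the parameter vector.
#' @param priors A [prior_spec()].
#' @param half Fit `"all"` trials or only the `"first"`/`"second"` half.
#' @param likelihood If `FALSE`, the data term is switched off and the object
#'   represents the prior alone (useful for prior-recovery checks).
#' @param parameterization `"noncentered"` (default) or `"centered"` random
#'   effects.
#' @return An object of class `foraging_posterior` with elements `lp_grad`
#'   (function of the unconstrained vector returning `list(lp, grad)`),
#'   `dim`, `init()`, `constrain()`, and the prepared event data.
#' @export
build_log_posterior <- function(data, variant = "FULL", priors = prior_spec(),
                                half = "all", likelihood = TRUE,
                                parameterization = c("noncentered", "centered")) {
  stopifnot(inherits(priors, "prior_spec"))
  parameterization <- match.arg(parameterization)
  centered <- parameterization == "centered"
  ev <- prepare_event_data(data, variant = variant, half = half)
  if (likelihood && length(ev$chosen) == 0L)
    stop("dataset contains no selection events beyond first clicks", call. = FALSE)
  pars <- ev$pars
  K <- length(pars)
  P <- length(ev$participants)
  m <- K * (K - 1L) / 2L
  loc <- priors$loc[pars]
  scale <- priors$scale[pars]
  rate <- priors$sd_rate
  eta <- priors$lkj_eta

  ib <- seq_len(K)
  isg <- K + seq_len(K)
  iy <- 2L * K + seq_len(m)
  iz <- 2L * K + m + seq_len(K * P)
  dim_q <- 2L * K + m + K * P

  corr_names <- character(0)
  if (m > 0) {
    for (i in 2:K) for (j in 1:(i - 1))
      corr_names <- c(corr_names, sprintf("corr[%s,%s]", pars[j], pars[i]))
  }
  retag <- if (centered) "theta" else "z"
  unconstrained_names <- c(paste0("beta[", pars, "]"),
                           paste0("log_sigma[", pars, "]"),
                           paste0("y[", seq_len(m), "]"),
                           paste0(retag, "[", rep(seq_len(P), each = K), ",",
                                  rep(pars, P), "]"))

  lp_grad <- function(q) {
    hier_lp_grad(q, ev$X, ev$ptr, ev$chosen, ev$part, K, P,
                 loc, scale, rate, eta, likelihood, ev$const_ll_total,
                 centered)
  }

  loglik_theta <- function(theta) {
    stopifnot(nrow(theta) == K, ncol(theta) == P)
    if (length(ev$chosen) == 0L) return(ev$const_ll_total)
    res <- cf_event_ll_grad(ev$X, ev$ptr, ev$chosen, ev$part, theta)
    res$ll + ev$const_ll_total
  }

  constrain <- function(q) {
    beta <- q[ib]; names(beta) <- pars
    sigma <- exp(q[isg]); names(sigma) <- pars
    L <- chol_from_y(q[iy], K)
    R <- tcrossprod(L)
    dimnames(R) <- list(pars, pars)
    if (centered) {
      theta <- matrix(q[iz], K, P)
      z <- solve(L, (theta - beta) / sigma)
    } else {
      z <- matrix(q[iz], K, P)
      theta <- beta + sigma * (L %*% z)
    }
    dimnames(theta) <- list(pars, ev$participants)
    list(beta = beta, sigma = sigma, corr = R, theta = theta, z = z)
  }

  init <- function() {
    beta0 <- loc + scale * stats::runif(K, -0.5, 0.5)
    re0 <- if (centered) {
      # participant coefficients start near the initial fixed effects
      rep(beta0, P) + 0.05 * abs(rep(beta0, P)) * stats::rnorm(K * P) +
        0.01 * stats::rnorm(K * P)
    } else {
      stats::runif(K * P, -0.5, 0.5)
    }
    c(beta0, stats::runif(K, -2.5, -1), stats::runif(m, -0.3, 0.3), re0)
  }

  structure(
    list(lp_grad = lp_grad, loglik_theta = loglik_theta, constrain = constrain,
         init = init, dim = dim_q, K = K, P = P, m = m, pars = pars,
         corr_names = corr_names, unconstrained_names = unconstrained_names,
         participants = ev$participants, events = ev, variant = variant,
         priors = priors, half = half, likelihood = likelihood,
         parameterization = parameterization),
    class = "foraging_posterior"
  )
}
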