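# Generalized Pareto fit to sample exceedances (profile-likelihood grid with
# a weakly informative prior on the shape, after Zhang & Stephens 2009).
# Returns the shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x[is.finite(x)])
  N <- length(x)
  if (N < 5L || x[N] <= 0) return(list(k = NaN, sigma = NaN))
  M <- 30L + floor(sqrt(N))
  j <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  if (xstar <= 0) xstar <- x[N] / 4
  theta <- 1 / x[N] + (1 - sqrt(M / (j - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(th) {
    xi <- mean(log1p(-th * x))
    if (!is.finite(xi) || xi == 0) return(-Inf)
    N * (log(-th / xi) - xi - 1)
  }, 0)
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- mean(log1p(-th_hat * x))
  sigma <- -k / th_hat
  # weakly informative prior shrinking k toward 0.5
  k <- (k * N + 5) / (N + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS leave-one-out cross-validation
#'
#' Estimates the expected log predictive density (ELPD) by leave-one-out
#' cross-validation with Pareto-smoothed importance sampling. The unit of
#' cross-validation is the single selection event. For each event the
#' importance ratios are the inverse pointwise likelihoods; the largest
#' `min(0.2 S, 3 sqrt(S))` ratios are replaced by expected order statistics
#' of a generalized Pareto distribution fitted to them, truncated at the raw
#' maximum. Events with a Pareto shape `k >= 0.7` are flagged as unreliable.
#'
#' @param x A `foraging_fit` with a stored log-likelihood matrix, or a
#'   numeric matrix of pointwise log-likelihoods (draws x events).
#' @return An object of class `foraging_loo` with elements `elpd`, `se`,
#'   `pointwise`, `pareto_k`, `mcse`, and `flagged`.
#' @export
psis_loo <- function(x) {
  ll <- if (inherits(x, "foraging_fit")) x$log_lik else x
  if (is.null(ll))
    stop("fit has no stored log-likelihood matrix (compute_loglik = FALSE?)",
         call. = FALSE)
  stopifnot(is.matrix(ll))
  if (any(!is.finite(ll)))
    stop("pointwise log-likelihood matrix contains non-finite values", call. = FALSE)
  S <- nrow(ll)
  n <- ncol(ll)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  mcse2 <- numeric(n)
  for (i in seq_len(n)) {
    lli <- ll[, i]
    lr <- -lli
    lr <- lr - max(lr)
    if (max(lr) - min(lr) < 1e-13) {
      # no posterior uncertainty in this event's density
      elpd_i[i] <- lli[1]
      k_i[i] <- -Inf
      next
    }
    khat <- -Inf
    if (tail_len >= 5L && tail_len < S) {
      ord <- order(lr)
      tail_idx <- ord[(S - tail_len + 1L):S]
      cutoff <- exp(lr[ord[S - tail_len]])
      exc <- exp(lr[tail_idx]) - cutoff
      if (sum(exc > 0) >= 5L) {
        fitk <- gpd_fit(exc)
        if (is.finite(fitk$k)) {
          khat <- fitk$k
          pr <- (seq_len(tail_len) - 0.5) / tail_len
          smoothed <- cutoff + vapply(pr, gpd_quantile, 0,
                                      k = fitk$k, sigma = fitk$sigma)
          smoothed <- pmin(smoothed, 1)  # ratios were shifted so max(raw) = 1
          lr[tail_idx[order(lr[tail_idx])]] <- log(smoothed)
        }
      }
    }
    lw <- lr - log_sum_exp(lr)
    elpd_i[i] <- log_sum_exp(lw + lli)
    k_i[i] <- khat
    wgt <- exp(lw)
    mcse2[i] <- sum(wgt^2 * (exp(lli - elpd_i[i]) - 1)^2)
  }
  structure(
    list(elpd = sum(elpd_i), se = sqrt(n * stats::var(elpd_i)),
         pointwise = elpd_i, pareto_k = k_i,
         mcse = sqrt(sum(mcse2)), n_draws = S, n_events = n,
         flagged = which(k_i >= 0.7)),
    class = "foraging_loo"
  )
}

#' @export
print.foraging_loo <- function(x, ...) {
  cat(sprintf("<foraging_loo> elpd %.1f (se %.1f), %d events, %d draws\n",
              x$elpd, x$se, x$n_events, x$n_draws))
  cat(sprintf("  Pareto k: %d event(s) with k >= 0.7\n", length(x$flagged)))
  invisible(x)
}

#' Compare models by ELPD difference
#'
#' Ranks PSIS-LOO results computed on the same selection events: the model
#' with the largest ELPD is anchored at an ELPD difference of zero, and the
#' standard error of each difference comes from the event-wise paired
#' differences of the pointwise contributions.
#'
#' @param ... Named `foraging_loo` objects, or a single named list of them.
#' @return An object of class `foraging_comparison`: a data frame with one
#'   row per model (`elpd`, `se`, `elpd_diff`, `se_diff`), best first.
#' @export
compare_foraging_models <- function(...) {
  loos <- list(...)
  if (length(loos) == 1L && !inherits(loos[[1]], "foraging_loo"))
    loos <- loos[[1]]
  if (!all(vapply(loos, inherits, TRUE, "foraging_loo")))
    stop("all arguments must be foraging_loo objects", call. = FALSE)
  if (is.null(names(loos)) || any(names(loos) == ""))
    names(loos) <- paste0("model", seq_along(loos))
  nev <- vapply(loos, `[[`, 0, "n_events")
  if (length(unique(nev)) != 1L)
    stop("models were evaluated on different numbers of events", call. = FALSE)
  elpd <- vapply(loos, `[[`, 0, "elpd")
  best <- which.max(elpd)
  n <- nev[[1]]
  rows <- lapply(seq_along(loos), function(i) {
    d <- loos[[i]]$pointwise - loos[[best]]$pointwise
    data.frame(model = names(loos)[i],
               elpd = elpd[[i]], se = loos[[i]]$se,
               elpd_diff = sum(d),
               se_diff = if (i == best) 0 else sqrt(n * stats::var(d)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$elpd), ]
  rownames(out) <- NULL
  class(out) <- c("foraging_comparison", "data.frame")
  out
}

#' @export
print.foraging_comparison <- function(x, ...) {
  cat("Model comparison (PSIS-LOO, best model at elpd_diff = 0):\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
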