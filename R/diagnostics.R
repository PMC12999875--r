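#' Split-chain potential scale reduction factor (r-hat)
#'
#' Each chain is split in half and the between/within-variance PSRF is
#' computed on the split chains. By default the draws are rank-normalized
#' first (ranked across all chains, then mapped through the normal quantile
#' function), the estimator whose r-hat < 1.01 convergence threshold this
#' package adopts; `rank_normalize = FALSE` gives the classic statistic on
#' the raw draws. Chains with zero variance (constant draws) return 1 by
#' convention.
#'
#' @param x A matrix of draws (iterations x chains) or a 3-d array
#'   (iterations x chains x parameters).
#' @param rank_normalize Rank-normalize the pooled draws before computing
#'   the split-chain statistic (default `TRUE`).
#' @return A single r-hat, or a named vector (one per parameter) for arrays.
#' @export
compute_rhat <- function(x, rank_normalize = TRUE) {
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- apply(x, 3, compute_rhat, rank_normalize = rank_normalize)
    names(out) <- dimnames(x)[[3]]
    return(out)
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L)
    stop("r-hat requires at least 2 chains", call. = FALSE)
  if (nrow(x) < 4L)
    stop("r-hat requires at least 4 iterations per chain", call. = FALSE)
  if (stats::var(as.numeric(x)) == 0) return(1)
  if (rank_normalize) {
    S <- length(x)
    z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (S + 1 / 4))
    x <- matrix(z, nrow(x), ncol(x))
  }
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[(nrow(x) - n + 1L):nrow(x), , drop = FALSE])
  mns <- colMeans(halves)
  vrs <- apply(halves, 2, stats::var)
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size for one parameter (iterations x chains), following
# the combined-chain autocorrelation estimator with Geyer's initial monotone
# positive sequence.
ess_one <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acov <- vapply(seq_len(m), function(c) {
    a <- stats::acf(x[, c], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(n))
  chain_var <- acov[1, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(colMeans(x))
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: sum of adjacent pairs, keep while positive and monotone decreasing
  max_pairs <- floor((n - 1) / 2)
  psum_prev <- Inf
  tau <- 1  # will accumulate 2 * sum of retained rho beyond lag 0 minus rho0 handling
  ssum <- rho[1]
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(p) || p < 0) break
    if (p > psum_prev) p <- psum_prev
    psum_prev <- p
    ssum <- ssum + p
  }
  tau <- max(2 * ssum - 1, 1 / log10(n * m + 1))
  ess <- n * m / tau
  min(ess, n * m * log10(n * m))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples; ties are broken toward the lowest lower bound.
#'
#' @param samples Numeric vector of posterior draws (`>= 2`).
#' @param mass Probability mass in `(0, 1)`; the package's summaries use
#'   0.53, 0.89 and 0.97.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(samples, mass = 0.97) {
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("`mass` must be a single value in (0, 1)", call. = FALSE)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)  # first minimum = lowest lower bound
  c(lower = x[i], upper = x[i + k - 1L])
}
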