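# Shared fixtures and independent oracles for the test suite.

# A small display with hand-chosen hues and positions; no randomness.
toy_display <- function(hues = c(24, 26, 20, 30),
                        x = c(0.1, 0.9, 0.5, 0.2),
                        y = c(0.1, 0.1, 0.8, 0.6),
                        is_target = c(TRUE, TRUE, TRUE, FALSE),
                        mu = 24, n_hues = 48, quota = length(hues)) {
  structure(list(
    items = data.frame(item_id = seq_along(hues), hue = hues, x = x, y = y,
                       is_target = is_target),
    mu = mu, n_hues = n_hues, quota = quota), class = "display")
}

# Straight-line likelihood evaluator: recomputes every predictor and the
# normalization from first principles, entirely without log-space tricks.
# Deliberately independent of the package implementation.
brute_force_trial_loglik <- function(display, sequence, params) {
  items <- display$items
  n_hues <- display$n_hues
  circ <- function(a, b) {
    d <- abs(a - b)
    min(d, n_hues - d)
  }
  remaining <- items$item_id
  prob <- 1
  prev <- NULL
  penult <- NULL
  for (j in seq_along(sequence)) {
    sel <- sequence[j]
    rows <- items[match(remaining, items$item_id), ]
    if (j == 1) {
      p <- rep(1 / nrow(rows), nrow(rows))
    } else {
      w <- numeric(nrow(rows))
      for (i in seq_len(nrow(rows))) {
        e <- -params[["rho_c"]] * circ(rows$hue[i], display$mu) -
          params[["rho_s"]] * circ(rows$hue[i], prev$hue) -
          params[["rho_delta"]] * sqrt((rows$x[i] - prev$x)^2 + (rows$y[i] - prev$y)^2)
        if (j >= 3) {
          v1 <- c(prev$x - penult$x, prev$y - penult$y)
          v2 <- c(rows$x[i] - prev$x, rows$y[i] - prev$y)
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          cosang <- max(-1, min(1, cosang))
          e <- e - params[["rho_psi"]] * (acos(cosang) / pi)
        }
        w[i] <- exp(e)
      }
      p <- w / sum(w)
    }
    k <- match(sel, remaining)
    prob <- prob * p[k]
    penult <- prev
    prev <- rows[k, ]
    remaining <- remaining[-k]
  }
  log(prob)
}

# central-difference gradient of a scalar function
numeric_gradient <- function(f, q, h = 1e-5) {
  vapply(seq_along(q), function(i) {
    qp <- q; qp[i] <- q[i] + h
    qm <- q; qm[i] <- q[i] - h
    (f(qp) - f(qm)) / (2 * h)
  }, numeric(1))
}

# small simulated dataset + fit, built once and reused across test files
.hf_cache <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.hf_cache$data)) {
    .hf_cache$data <- simulate_experiment(
      group_parameters(), session_spec(n_trials = 4, shift = 0),
      n_participants = 4, seed = 101)
  }
  .hf_cache$data
}

tiny_fit <- function() {
  if (is.null(.hf_cache$fit)) {
    .hf_cache$fit <- fit_foraging(tiny_dataset(), chains = 2, warmup = 200,
                                  draws = 200, seed = 202,
                                  rhat_action = "none")
  }
  .hf_cache$fit
}
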