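# No-U-Turn sampler with dual-averaging step-size adaptation and windowed
# diagonal mass-matrix estimation (slice-sampling tree variant, doubling
# until the trajectory starts to double back). Self-contained: the only
# model interface is lp_grad(q) -> list(lp, grad).

nuts_chain <- function(lp_grad, q0, n_warmup, n_draws, control = list()) {
  ctl <- utils::modifyList(list(max_treedepth = 10, warmup_treedepth = 9,
                                adapt_delta = 0.8,
                                init_buffer = 75, term_buffer = 150,
                                base_window = 25, max_delta_energy = 1000),
                           control)
  d <- length(q0)
  inv_mass <- rep(1, d)
  max_td <- ctl$max_treedepth
  dmax <- ctl$max_delta_energy

  cur <- lp_grad(q0)
  if (!is.finite(cur$lp)) stop("initial point has non-finite log density", call. = FALSE)
  q <- q0; lp <- cur$lp; grad <- cur$grad

  kinetic <- function(r) 0.5 * sum(inv_mass * r * r)

  leapfrog <- function(q, r, grad, eps) {
    r <- r + (eps / 2) * grad
    q <- q + eps * (inv_mass * r)
    lg <- lp_grad(q)
    if (!all(is.finite(lg$grad)) || !is.finite(lg$lp)) {
      lg$lp <- -Inf
      lg$grad <- rep(0, d)
    }
    r <- r + (eps / 2) * lg$grad
    list(q = q, r = r, lp = lg$lp, grad = lg$grad)
  }

  no_uturn <- function(qm, qp, rm, rp) {
    dq <- qp - qm
    sum(dq * (inv_mass * rm)) >= 0 && sum(dq * (inv_mass * rp)) >= 0
  }

  find_epsilon <- function(q, lp, grad) {
    eps <- 0.1
    r0 <- stats::rnorm(d) / sqrt(inv_mass)
    j0 <- lp - kinetic(r0)
    st <- leapfrog(q, r0, grad, eps)
    la <- st$lp - kinetic(st$r) - j0
    if (!is.finite(la)) la <- -Inf
    a <- if (la > log(0.5)) 1 else -1
    for (iter in 1:50) {
      if (!(a * la > -a * log(2))) break
      eps <- eps * 2^a
      st <- leapfrog(q, r0, grad, eps)
      la <- st$lp - kinetic(st$r) - j0
      if (!is.finite(la)) la <- -Inf
    }
    eps
  }

  # recursive doubling; returns subtree summary
  build_tree <- function(q, r, grad, lp, log_u, v, j, eps, joint0) {
    if (j == 0L) {
      st <- leapfrog(q, r, grad, v * eps)
      joint <- st$lp - kinetic(st$r)
      if (!is.finite(joint)) joint <- -Inf
      n1 <- as.integer(log_u <= joint)
      div <- (joint - log_u) < -dmax
      alpha <- min(1, exp(joint - joint0))
      if (!is.finite(alpha)) alpha <- 0
      list(qm = st$q, rm = st$r, gm = st$grad, lpm = st$lp,
           qp = st$q, rp = st$r, gp = st$grad, lpp = st$lp,
           qprop = st$q, gprop = st$grad, lpprop = st$lp,
           n = n1, s = !div, alpha = alpha, nalpha = 1L, div = div)
    } else {
      t1 <- build_tree(q, r, grad, lp, log_u, v, j - 1L, eps, joint0)
      if (!t1$s) return(t1)
      if (v == -1) {
        t2 <- build_tree(t1$qm, t1$rm, t1$gm, t1$lpm, log_u, v, j - 1L, eps, joint0)
        t1$qm <- t2$qm; t1$rm <- t2$rm; t1$gm <- t2$gm; t1$lpm <- t2$lpm
      } else {
        t2 <- build_tree(t1$qp, t1$rp, t1$gp, t1$lpp, log_u, v, j - 1L, eps, joint0)
        t1$qp <- t2$qp; t1$rp <- t2$rp; t1$gp <- t2$gp; t1$lpp <- t2$lpp
      }
      ntot <- t1$n + t2$n
      if (t2$n > 0L && stats::runif(1) < t2$n / ntot) {
        t1$qprop <- t2$qprop; t1$gprop <- t2$gprop; t1$lpprop <- t2$lpprop
      }
      t1$n <- ntot
      t1$alpha <- t1$alpha + t2$alpha
      t1$nalpha <- t1$nalpha + t2$nalpha
      t1$div <- t1$div || t2$div
      t1$s <- t2$s && no_uturn(t1$qm, t1$qp, t1$rm, t1$rp)
      t1
    }
  }

  # dual averaging state
  eps <- find_epsilon(q, lp, grad)
  da_mu <- log(10 * eps)
  da_h <- 0; da_leps_bar <- 0; da_count <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  delta <- ctl$adapt_delta

  # mass adaptation windows
  n_total <- n_warmup + n_draws
  init_buf <- ctl$init_buffer; term_buf <- ctl$term_buffer; base_w <- ctl$base_window
  if (n_warmup > 0 && init_buf + term_buf + base_w > n_warmup) {
    init_buf <- max(1L, floor(0.15 * n_warmup))
    term_buf <- max(1L, floor(0.10 * n_warmup))
    base_w <- max(1L, n_warmup - init_buf - term_buf)
  }
  window_ends <- integer(0)
  if (n_warmup > init_buf + term_buf) {
    pos <- init_buf; w <- base_w
    while (pos + w <= n_warmup - term_buf) {
      e <- pos + w
      if (pos + 3L * w > n_warmup - term_buf) e <- n_warmup - term_buf
      window_ends <- c(window_ends, e)
      pos <- e
      w <- 2L * w
    }
  }
  welford_n <- 0; welford_m <- rep(0, d); welford_s <- rep(0, d)

  draws <- matrix(NA_real_, n_draws, d)
  lp_out <- numeric(n_draws)
  n_div <- 0L
  td_out <- integer(n_draws)
  accept_sum <- 0

  for (it in seq_len(n_total)) {
    r0 <- stats::rnorm(d) / sqrt(inv_mass)
    joint0 <- lp - kinetic(r0)
    log_u <- joint0 - stats::rexp(1)
    qm <- q; qp <- q; rm <- r0; rp <- r0; gm <- grad; gp <- grad
    lpm <- lp; lpp <- lp
    qprop <- q; gprop <- grad; lpprop <- lp
    n <- 1L; s <- TRUE; j <- 0L
    alpha <- 0; nalpha <- 0L; diverged <- FALSE
    cap <- if (it <= n_warmup) ctl$warmup_treedepth else max_td
    while (s && j < cap) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == -1) {
        tt <- build_tree(qm, rm, gm, lpm, log_u, v, j, eps, joint0)
        qm <- tt$qm; rm <- tt$rm; gm <- tt$gm; lpm <- tt$lpm
      } else {
        tt <- build_tree(qp, rp, gp, lpp, log_u, v, j, eps, joint0)
        qp <- tt$qp; rp <- tt$rp; gp <- tt$gp; lpp <- tt$lpp
      }
      if (tt$s && tt$n > 0L && stats::runif(1) < min(1, tt$n / n)) {
        qprop <- tt$qprop; gprop <- tt$gprop; lpprop <- tt$lpprop
      }
      n <- n + tt$n
      alpha <- alpha + tt$alpha
      nalpha <- nalpha + tt$nalpha
      diverged <- diverged || tt$div
      s <- tt$s && no_uturn(qm, qp, rm, rp)
      j <- j + 1L
    }
    q <- qprop; grad <- gprop; lp <- lpprop
    astat <- if (nalpha > 0L) alpha / nalpha else 0

    if (it <= n_warmup) {
      # step size
      da_count <- da_count + 1
      da_h <- (1 - 1 / (da_count + t0)) * da_h + (delta - astat) / (da_count + t0)
      leps <- da_mu - sqrt(da_count) / gamma * da_h
      wda <- da_count^(-kappa)
      da_leps_bar <- wda * leps + (1 - wda) * da_leps_bar
      eps <- exp(leps)
      # mass accumulation
      if (it > init_buf && it <= n_warmup - term_buf) {
        welford_n <- welford_n + 1
        dlt <- q - welford_m
        welford_m <- welford_m + dlt / welford_n
        welford_s <- welford_s + dlt * (q - welford_m)
      }
      if (it %in% window_ends && welford_n > 2) {
        v_est <- welford_s / (welford_n - 1)
        inv_mass <- v_est * (welford_n / (welford_n + 5)) +
          1e-3 * (5 / (welford_n + 5))
        welford_n <- 0; welford_m <- rep(0, d); welford_s <- rep(0, d)
        eps <- find_epsilon(q, lp, grad)
        da_mu <- log(10 * eps)
        da_h <- 0; da_leps_bar <- 0; da_count <- 0
      }
      if (it == n_warmup) eps <- exp(da_leps_bar)
    } else {
      k <- it - n_warmup
      draws[k, ] <- q
      lp_out[k] <- lp
      td_out[k] <- j
      if (diverged) n_div <- n_div + 1L
      accept_sum <- accept_sum + astat
    }
  }

  list(draws = draws, lp = lp_out, divergences = n_div,
       treedepth = td_out, stepsize = eps, inv_mass = inv_mass,
       accept_rate = accept_sum / max(1, n_draws))
}
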