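# No-U-Turn Sampler (tree-doubling HMC with slice sampling and
# dual-averaging step-size adaptation), written against a generic
# log-density interface: `logp(x)` must return `list(value, grad)`.
# A diagonal mass matrix is estimated from the second half of warmup.

nuts_sample <- function(logp, init, n_samples, n_warmup = 1000, seed = 1L,
                        target_accept = 0.8, max_depth = 10) {
  set.seed(seed)
  d <- length(init)
  x <- init
  cur <- logp(x)
  if (!is.finite(cur$value)) stop("nuts_sample: non-finite log density at init")
  mass <- rep(1, d)     # diagonal metric, updated mid-warmup
  inv_mass <- 1 / mass

  leapfrog <- function(x, p, eps, gr) {
    p <- p + 0.5 * eps * gr$grad
    x <- x + eps * inv_mass * p
    gr2 <- logp(x)
    p <- p + 0.5 * eps * gr2$grad
    list(x = x, p = p, lp = gr2)
  }
  joint <- function(lp, p) lp$value - 0.5 * sum(inv_mass * p^2)

  # reasonable initial step size by matching ~50% acceptance of one step
  find_eps <- function(x, cur) {
    eps <- 0.1
    p <- stats::rnorm(d, 0, sqrt(mass))
    h0 <- joint(cur, p)
    st <- leapfrog(x, p, eps, cur)
    h1 <- joint(st$lp, st$p)
    if (!is.finite(h1)) h1 <- -Inf
    a <- if (h1 - h0 > log(0.5)) 1 else -1
    while (a * (joint(st$lp, st$p) - h0) > -a * log(2)) {
      eps <- eps * 2^a
      if (eps < 1e-10 || eps > 1e2) break
      st <- leapfrog(x, p, eps, cur)
      if (!is.finite(st$lp$value)) { eps <- eps / 2^a; break }
    }
    eps
  }

  DIVERGENCE <- 1000
  n_div <- 0L

  build_tree <- function(x, p, lp, logu, dir, depth, eps, h0) {
    if (depth == 0L) {
      st <- leapfrog(x, p, dir * eps, lp)
      h <- joint(st$lp, st$p)
      if (!is.finite(h)) h <- -Inf
      div <- (logu > h + DIVERGENCE) || !is.finite(h)
      nvalid <- as.integer(logu <= h)
      alpha <- min(1, exp(h - h0))
      list(xm = st$x, pm = st$p, lpm = st$lp, xp = st$x, pp = st$p, lpp = st$lp,
           xprop = st$x, lpprop = st$lp, nvalid = nvalid, stop = div,
           alpha = alpha, nalpha = 1L, div = div)
    } else {
      t1 <- build_tree(x, p, lp, logu, dir, depth - 1L, eps, h0)
      if (t1$stop) return(t1)
      if (dir == -1) {
        t2 <- build_tree(t1$xm, t1$pm, t1$lpm, logu, dir, depth - 1L, eps, h0)
        t1$xm <- t2$xm; t1$pm <- t2$pm; t1$lpm <- t2$lpm
      } else {
        t2 <- build_tree(t1$xp, t1$pp, t1$lpp, logu, dir, depth - 1L, eps, h0)
        t1$xp <- t2$xp; t1$pp <- t2$pp; t1$lpp <- t2$lpp
      }
      ntot <- t1$nvalid + t2$nvalid
      if (t2$nvalid > 0L && stats::runif(1) < t2$nvalid / max(ntot, 1L)) {
        t1$xprop <- t2$xprop; t1$lpprop <- t2$lpprop
      }
      dx <- t1$xp - t1$xm
      uturn <- (sum(dx * (inv_mass * t1$pm)) < 0) || (sum(dx * (inv_mass * t1$pp)) < 0)
      t1$nvalid <- ntot
      t1$stop <- t2$stop || uturn
      t1$div <- t1$div || t2$div
      t1$alpha <- t1$alpha + t2$alpha
      t1$nalpha <- t1$nalpha + t2$nalpha
      t1
    }
  }

  eps <- find_eps(x, cur)
  mu <- log(10 * eps)
  logeps_bar <- 0; hbar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  m_da <- 0L

  total <- n_warmup + n_samples
  draws <- matrix(NA_real_, n_samples, d)
  # draws collected in (45%, 75%] of warmup feed the diagonal mass
  # estimate; step-size adaptation restarts afterwards
  win_start <- floor(0.45 * n_warmup)
  win_end <- floor(0.75 * n_warmup)
  win <- matrix(NA_real_, max(win_end - win_start, 1), d)
  wj <- 0L

  for (it in seq_len(total)) {
    p0 <- stats::rnorm(d, 0, sqrt(mass))
    h0 <- joint(cur, p0)
    logu <- h0 - stats::rexp(1)   # slice variable on log scale
    xm <- x; xp <- x; pm <- p0; pp <- p0; lpm <- cur; lpp <- cur
    xprop <- x; lpprop <- cur
    nvalid <- 1L; depth <- 0L; stop_ <- FALSE
    alpha_sum <- 0; nalpha <- 0L
    while (!stop_ && depth < max_depth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      if (dir == -1) {
        t <- build_tree(xm, pm, lpm, logu, dir, depth, eps, h0)
        xm <- t$xm; pm <- t$pm; lpm <- t$lpm
      } else {
        t <- build_tree(xp, pp, lpp, logu, dir, depth, eps, h0)
        xp <- t$xp; pp <- t$pp; lpp <- t$lpp
      }
      if (t$div) n_div <- n_div + 1L
      if (!t$stop && t$nvalid > 0L &&
          stats::runif(1) < t$nvalid / max(nvalid, 1L)) {
        xprop <- t$xprop; lpprop <- t$lpprop
      }
      nvalid <- nvalid + t$nvalid
      alpha_sum <- alpha_sum + t$alpha
      nalpha <- nalpha + t$nalpha
      dx <- xp - xm
      stop_ <- t$stop || (sum(dx * (inv_mass * pm)) < 0) ||
        (sum(dx * (inv_mass * pp)) < 0)
      depth <- depth + 1L
    }
    x <- xprop; cur <- lpprop

    if (it <= n_warmup) {
      # dual averaging
      m_da <- m_da + 1L
      m <- m_da
      accept_prob <- if (nalpha > 0L) alpha_sum / nalpha else 0
      hbar <- (1 - 1 / (m + t0)) * hbar + (target_accept - accept_prob) / (m + t0)
      logeps <- mu - sqrt(m) / gamma * hbar
      w <- m^(-kappa)
      logeps_bar <- w * logeps + (1 - w) * logeps_bar
      eps <- exp(logeps)
      if (it > win_start && it <= win_end) {
        wj <- wj + 1L
        win[wj, ] <- x
      }
      if (it == win_end && wj > 10L) {
        v <- apply(win[seq_len(wj), , drop = FALSE], 2, stats::var)
        mass <- 1 / pmax(v, 1e-8)
        inv_mass <- 1 / mass
        # retune the step size under the new metric
        eps <- find_eps(x, cur)
        mu <- log(10 * eps)
        logeps_bar <- 0; hbar <- 0; m_da <- 0L
      }
      if (it == n_warmup) eps <- exp(logeps_bar)
    } else {
      draws[it - n_warmup, ] <- x
    }
  }
  list(draws = draws, n_divergent = n_div, step_size = eps)
}
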