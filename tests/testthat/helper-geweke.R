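# Joint-distribution ("getting it right") harness: alternate MCMC
# transitions on (parameters, latents) given data with redraws of the data
# given the latents; at stationarity every parameter's marginal equals its
# prior, which a direct prior sampler provides for comparison.

geweke_spec <- function() {
  list(n = 3, K = 6, r_depth = 1000, d0 = 1e-4, d1 = 0.05,
       qn = 2, qvar = 0.04, delta_t = 0.5,
       priors = list(m_a1 = 1, v_a1 = 0.25, m_a2 = 1e-9, v_a2 = 1e-18,
                     v_b = 1e-20, v_g = 1, w_shape = 5, w_rate = 0.5,
                     a_shape = 2, a_rate = 1, zb_a = 1, zb_b = 1,
                     zg_a = 1, zg_b = 1, x0_m = log(1e8), x0_v = 1))
}

rtrunc_lower <- function(n, m, s, lower = 0) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat { v <- stats::rnorm(1, m, s); if (v >= lower) break }
    out[i] <- v
  }
  out
}

geweke_draw_prior <- function(sp) {
  pr <- sp$priors
  n <- sp$n; K <- sp$K
  alpha <- stats::rgamma(1, pr$a_shape, rate = pr$a_rate)
  c <- integer(n); c[1] <- 1L; cnt <- 1L
  for (i in seq_len(n)[-1]) {
    m <- sample(length(cnt) + 1L, 1, prob = c(cnt, alpha))
    if (m > length(cnt)) cnt <- c(cnt, 0L)
    cnt[m] <- cnt[m] + 1L; c[i] <- m
  }
  M <- length(cnt)
  theta <- stats::rbeta(1, pr$zb_a, pr$zb_b)
  zb <- matrix(stats::rbinom(M * M, 1, theta), M, M); diag(zb) <- 0L
  storage.mode(zb) <- "integer"
  b <- matrix(stats::rnorm(M * M, 0, sqrt(pr$v_b)), M, M); diag(b) <- 0
  a1 <- rtrunc_lower(n, pr$m_a1, sqrt(pr$v_a1))
  a2 <- rtrunc_lower(n, pr$m_a2, sqrt(pr$v_a2))
  sw2 <- pr$w_rate / stats::rgamma(1, pr$w_shape)
  logX <- matrix(0, n, K)
  logX[, 1] <- stats::rnorm(n, pr$x0_m, sqrt(pr$x0_v))
  for (k in seq_len(K - 1)) {
    x <- exp(logX[, k])
    S <- vapply(seq_len(M), function(m) sum(x[c == m]), numeric(1))
    FF <- vapply(seq_len(n), function(i) {
      ms <- setdiff(seq_len(M), c[i])
      a1[i] - a2[i] * x[i] + sum(b[c[i], ms] * zb[c[i], ms] * S[ms])
    }, numeric(1))
    logX[, k + 1] <- stats::rnorm(n, logX[, k] + sp$delta_t * FF,
                                  sqrt(sp$delta_t * sw2))
  }
  list(logX = list(logX), a1 = a1, a2 = a2, c = c, b = b, zb = zb,
       gam = matrix(0, 0, M), zg = matrix(0L, 0, M), sw2 = sw2,
       alpha = alpha, prop_sd = rep(0.3, n))
}

geweke_draw_data <- function(sp, state) {
  n <- sp$n; K <- sp$K
  X <- exp(state$logX[[1]])
  Y <- matrix(0, n, K); qmean <- numeric(K)
  for (k in seq_len(K)) {
    rel <- X[, k] / sum(X[, k])
    eps <- sp$d0 / pmax(rel, 1e-12) + sp$d1
    Y[, k] <- stats::rnbinom(n, size = 1 / eps, mu = sp$r_depth * rel)
    qmean[k] <- mean(stats::rnorm(sp$qn, log(sum(X[, k])), sqrt(sp$qvar)))
  }
  list(subjects = list(list(Y = Y, r = rep(sp$r_depth, K),
                            qn = rep(sp$qn, K), qmean = qmean,
                            qvar = rep(sp$qvar, K),
                            delta = rep(sp$delta_t, K - 1),
                            H = matrix(0, 0, K))),
       d0 = sp$d0, d1 = sp$d1, relfloor = 1e-12)
}

# returns matrices of successive-conditional draws and direct prior draws
# for (growth[1], process variance, module count, concentration, a2[1])
run_geweke <- function(n_iter = 40000, thin = 25, sweeps_per_redraw = 3,
                       seed_chain = 103, seed_prior = 123) {
  sp <- geweke_spec()
  ctl <- list(n_sweeps = as.integer(sweeps_per_redraw), do_latents = TRUE,
              do_coeffs = TRUE, do_ind_b = TRUE, do_ind_g = TRUE,
              do_modules = TRUE, do_sw2 = TRUE, do_alpha = TRUE,
              adapt = FALSE, record_start = 0L, record_thin = 1L,
              latent_every = 0L)
  set.seed(seed_chain)
  state <- geweke_draw_prior(sp)
  dat <- geweke_draw_data(sp, state)
  n_keep <- n_iter %/% thin
  chain <- matrix(NA_real_, n_keep, 5)
  for (it in seq_len(n_iter)) {
    res <- glvmod:::cpp_run_gibbs(state, dat, sp$priors, ctl)
    state <- res$state
    dat <- geweke_draw_data(sp, state)
    if (it %% thin == 0) {
      chain[it %/% thin, ] <- c(state$a1[1], state$sw2, max(state$c),
                                state$alpha, state$a2[1])
    }
  }
  set.seed(seed_prior)
  prior <- t(replicate(n_keep, {
    s <- geweke_draw_prior(sp)
    c(s$a1[1], s$sw2, max(s$c), s$alpha, s$a2[1])
  }))
  colnames(chain) <- colnames(prior) <-
    c("growth", "process_var", "n_modules", "concentration",
      "self_interaction")
  list(chain = chain, prior = prior)
}
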