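# small helper: single-taxon noiseless logistic study
logistic_study <- function(K = 40, a1 = 1, a2 = 1e-9, x0 = 1e6,
                           n_qpcr = 3, qpcr_sdlog = 0.02, depth = 50000,
                           seed = 1) {
  set.seed(seed)
  truth <- glv_params(a1, a2, 1, matrix(0, 1, 1))
  simulate_cohort(truth, times = seq(0, K - 1), x0 = matrix(x0, 1, 1),
                  d0 = 0, d1 = 1e-4, qpcr_sdlog = qpcr_sdlog,
                  depth = depth, n_qpcr_replicates = n_qpcr, floor = 1)
}

test_that("empirical priors come from logistic fits with 1e4x inflation", {
  set.seed(2)
  truth <- glv_params(1, 1e-9, 1, matrix(0, 1, 1))
  study <- simulate_cohort(truth, times = 0:20, x0 = matrix(1e6, 1, 1),
                           d0 = 0, d1 = 1e-6, qpcr_sdlog = 0.001, floor = 1)
  pr <- empirical_priors(study)
  expect_equal(pr$m_a1, 1, tolerance = 0.1)
  expect_equal(pr$growth_summary[["mean_doubling_days"]],
               log(2) / pr$m_a1)
  # the inflation factor scales the variances exactly
  pr1 <- empirical_priors(study, inflate = 1)
  expect_equal(pr$v_a1, 1e4 * pr1$v_a1)
  expect_equal(pr$v_a2, 1e4 * pr1$v_a2)
})

test_that("degenerate trajectories fall back with a warning", {
  taxa <- data.frame(id = c("A", "B", "C", "D", "E"))
  counts <- list(S1 = matrix(1000, 5, 6))
  study <- glvmod:::new_glv_study(taxa, "S1", list(S1 = 0:5), counts,
                                  NULL, NULL)
  expect_warning(pr <- empirical_priors(study), "degenerate|default")
  expect_true(is.finite(pr$m_a1))
})

test_that("identical seeds give bitwise-identical posteriors", {
  study <- logistic_study()
  cfg <- inference_config(n_burnin = 50, n_samples = 50, seed = 7)
  d <- list(d0 = 0, d1 = 1e-4)
  f1 <- run_mcmc(study, d, cfg)
  f2 <- run_mcmc(study, d, cfg)
  expect_identical(f1$growth, f2$growth)
  expect_identical(f1$latents, f2$latents)
  expect_identical(f1$process_var, f2$process_var)
})

test_that("growth and self-interaction recover on dense logistic data", {
  study <- logistic_study(K = 40)
  cfg <- inference_config(n_burnin = 1000, n_samples = 1000, seed = 3)
  fit <- run_mcmc(study, list(d0 = 0, d1 = 1e-4), cfg,
                  priors = default_priors())
  expect_equal(stats::median(fit$growth[, 1]), 1, tolerance = 0.15)
  expect_equal(stats::median(fit$self_interaction[, 1]), 1e-9,
               tolerance = 0.25)
  # positivity truncation holds on every draw
  expect_true(all(fit$growth > 0))
  expect_true(all(fit$self_interaction >= 0))
  # latent MH acceptance lands in a workable band after adaptation
  expect_true(all(fit$acceptance > 0.1 & fit$acceptance < 0.7))
})

test_that("independent taxa keep a low edge inclusion under sparsity", {
  set.seed(4)
  truth <- glv_params(c(1, 0.8), c(1e-9, 2e-9), 1:2, matrix(0, 2, 2),
                      process_var = 0.01)
  study <- simulate_cohort(truth, times = 0:25,
                           x0 = matrix(c(1e7, 1e7), 2, 1),
                           trajectories = "stochastic", dt = 1,
                           qpcr_sdlog = 0.05, floor = 1)
  cfg <- inference_config(n_burnin = 500, n_samples = 500, seed = 5,
                          module_learning = "off",
                          sparsity_prior = "strong")
  fit <- run_mcmc(study, list(d0 = 4.2e-8, d1 = 6.05e-2), cfg)
  expect_lt(mean(fit$interaction_indicators[1, 2, ]), 0.2)
  expect_lt(mean(fit$interaction_indicators[2, 1, ]), 0.2)
})

test_that("tight qPCR pins the latent totals to the replicates", {
  study <- logistic_study(K = 15, qpcr_sdlog = 0.01)
  cfg <- inference_config(n_burnin = 400, n_samples = 400, seed = 6,
                          qpcr_sigma2 = 1e-8, latent_every = 5)
  fit <- run_mcmc(study, list(d0 = 0, d1 = 1e-4), cfg,
                  priors = default_priors())
  lat <- fit$latents[[length(fit$latents)]][[1]]
  q <- study$qpcr
  for (k in c(5, 10)) {
    geo <- exp(mean(log(q$value[q$time == study$times$S1[k]])))
    expect_equal(exp(lat[1, k]), geo, tolerance = 0.01)
  }
})

test_that("concentration sampler matches 1-D quadrature", {
  # fixed partition: N = 3 taxa in M = 2 modules; data never touched
  sp <- geweke_spec()
  pr <- sp$priors
  set.seed(8)
  state <- geweke_draw_prior(sp)
  state$c <- c(1L, 1L, 2L)
  state$b <- matrix(0, 2, 2); state$zb <- matrix(0L, 2, 2)
  state$gam <- matrix(0, 0, 2); state$zg <- matrix(0L, 0, 2)
  dat <- geweke_draw_data(sp, state)
  ctl <- list(n_sweeps = 20000L, do_latents = FALSE, do_coeffs = FALSE,
              do_ind_b = FALSE, do_ind_g = FALSE, do_modules = FALSE,
              do_sw2 = FALSE, do_alpha = TRUE, adapt = FALSE,
              record_start = 1L, record_thin = 1L, latent_every = 0L)
  res <- glvmod:::cpp_run_gibbs(state, dat, pr, ctl)
  draws <- as.numeric(res$samples$alpha)
  # posterior over alpha given M occupied modules among N taxa
  M <- 2; N <- 3
  dens <- function(a) {
    stats::dgamma(a, pr$a_shape, rate = pr$a_rate) * a^M *
      exp(lgamma(a) - lgamma(a + N))
  }
  num <- stats::integrate(function(a) a * dens(a), 0, 60)$value
  den <- stats::integrate(dens, 0, 60)$value
  expect_equal(mean(draws), num / den, tolerance = 0.05)
})

test_that("concentration moves with the module count", {
  sp <- geweke_spec()
  base_state <- function(part) {
    set.seed(9)
    st <- geweke_draw_prior(sp)
    M <- max(part)
    st$c <- as.integer(part)
    st$b <- matrix(0, M, M); st$zb <- matrix(0L, M, M)
    st$gam <- matrix(0, 0, M); st$zg <- matrix(0L, 0, M)
    st
  }
  ctl <- list(n_sweeps = 4000L, do_latents = FALSE, do_coeffs = FALSE,
              do_ind_b = FALSE, do_ind_g = FALSE, do_modules = FALSE,
              do_sw2 = FALSE, do_alpha = TRUE, adapt = FALSE,
              record_start = 1L, record_thin = 1L, latent_every = 0L)
  st1 <- base_state(c(1, 1, 1))
  stN <- base_state(c(1, 2, 3))
  dat <- geweke_draw_data(sp, st1)
  prior_mean <- sp$priors$a_shape / sp$priors$a_rate
  m1 <- mean(glvmod:::cpp_run_gibbs(st1, dat, sp$priors, ctl)$samples$alpha)
  mN <- mean(glvmod:::cpp_run_gibbs(stN, dat, sp$priors, ctl)$samples$alpha)
  expect_lt(m1, prior_mean)
  expect_gt(mN, prior_mean)
})

test_that("indicator update matches the hand-integrated two-point case", {
  # 1 subject, 2 taxa in 2 modules, K = 2: a single transition per taxon.
  # With everything else fixed the inclusion probability of the 1 -> 2
  # edge has a closed form from one Gaussian integral.
  sp <- geweke_spec()
  pr <- sp$priors
  pr$v_b <- 1e-18
  logX <- matrix(c(log(1e9), log(1e9) + 0.8,
                   log(2e9), log(2e9) + 0.1), 2, 2, byrow = TRUE)
  state <- list(logX = list(logX), a1 = c(0.5, 0.5), a2 = c(0, 0),
                c = 1:2, b = matrix(0, 2, 2), zb = matrix(0L, 2, 2),
                gam = matrix(0, 0, 2), zg = matrix(0L, 0, 2),
                sw2 = 0.04, alpha = 1, prop_sd = c(0.2, 0.2))
  dat <- list(subjects = list(list(Y = matrix(c(10, 10, 10, 10), 2, 2),
                                   r = c(20, 20), qn = c(0, 0),
                                   qmean = c(0, 0), qvar = c(1, 1),
                                   delta = 1, H = matrix(0, 0, 2))),
              d0 = 0, d1 = 0.05, relfloor = 1e-12)
  ctl <- list(n_sweeps = 40000L, do_latents = FALSE, do_coeffs = FALSE,
              do_ind_b = TRUE, do_ind_g = FALSE, do_modules = FALSE,
              do_sw2 = FALSE, do_alpha = FALSE, adapt = FALSE,
              record_start = 1L, record_thin = 1L, latent_every = 0L)
  set.seed(10)
  res <- glvmod:::cpp_run_gibbs(state, dat, pr, ctl)
  # column-major taxon-level layout: entry [i=1, j=2] = row 3 of the
  # flattened n^2 block (effect of taxon 2 on taxon 1)
  p_emp <- mean(res$samples$zb_taxon[3, ])

  # closed form for the 1 <- 2 edge, marginalizing the coefficient:
  # residual e = D - a1, regressor g = x_2(0), weight w = delta / sw2
  e <- 0.8 - 0.5; g <- 2e9; w <- 1 / 0.04
  Sw <- w * g^2; h <- w * g * e
  lml <- -0.5 * log1p(pr$v_b * Sw) + 0.5 * pr$v_b * h^2 / (1 + pr$v_b * Sw)
  # collapsed Beta-Bernoulli prior odds given the opposite edge's state:
  # both states are visited; enumerate the 2-indicator joint exactly
  e2 <- 0.1 - 0.5; g2 <- 1e9
  Sw2 <- w * g2^2; h2 <- w * g2 * e2
  lml2 <- -0.5 * log1p(pr$v_b * Sw2) +
    0.5 * pr$v_b * h2^2 / (1 + pr$v_b * Sw2)
  # joint prior over (z12, z21) under Beta(1,1): P proportional to
  # B(a + k, b + 2 - k) / B(a, b) with k = z12 + z21
  pri <- function(k) beta(1 + k, 1 + 2 - k) / beta(1, 1)
  w00 <- pri(0); w10 <- pri(1) * exp(lml); w01 <- pri(1) * exp(lml2)
  w11 <- pri(2) * exp(lml + lml2)
  p_exact <- (w10 + w11) / (w00 + w10 + w01 + w11)
  expect_equal(p_emp, p_exact, tolerance = 0.02)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(12)
  x <- matrix(rnorm(4000), 2000, 2)
  expect_equal(split_rhat(x), 1, tolerance = 0.01)
  y <- cbind(rnorm(2000), rnorm(2000, 10))
  expect_gt(split_rhat(y), 2)
  expect_error(split_rhat(matrix(1:3, 3, 1)), "at least 4")
})

test_that("rhat table flags variables at the 1.05 threshold", {
  study <- logistic_study(K = 12)
  d <- list(d0 = 0, d1 = 1e-4)
  fits <- lapply(1:2, function(s) {
    run_mcmc(study, d, inference_config(n_burnin = 100, n_samples = 200,
                                        seed = s))
  })
  tab <- rhat(fits)
  expect_true(all(c("variable", "rhat", "flagged") %in% names(tab)))
  expect_identical(tab$flagged, tab$rhat >= 1.05)
})

test_that("posterior stores round-trip bit-exactly", {
  study <- logistic_study(K = 10)
  fit <- run_mcmc(study, list(d0 = 0, d1 = 1e-4),
                  inference_config(n_burnin = 20, n_samples = 20, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  write_posterior(fit, path)
  expect_identical(read_posterior(path), fit)
})
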