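test_that("module interactions expand to the taxon-level matrix", {
  b <- matrix(c(0, 0, 0.3, 0), 2, 2)   # b[1,2] = 0.3: module 2 promotes 1
  p <- glv_params(c(1, 1), c(0.1, 0.2), c(1, 2), b)
  expect_equal(expand_to_taxa(p),
               matrix(c(-0.1, 0, 0.3, -0.2), 2, 2))

  p0 <- glv_params(c(1, 1, 1), c(0.1, 0.2, 0.3), c(1, 2, 1),
                   matrix(0.5, 2, 2),
                   interaction_indicators = matrix(0, 2, 2))
  expect_true(all(expand_to_taxa(p0)[row(diag(3)) != col(diag(3))] == 0))

  # element-by-element check against the definition on a 3-taxon/2-module
  # system
  b2 <- matrix(c(0, -0.2, 0.4, 0), 2, 2)
  p2 <- glv_params(c(1, 1, 1), c(0.1, 0.2, 0.3), c(1, 2, 1), b2)
  A <- expand_to_taxa(p2)
  cm <- p2$modules
  for (i in 1:3) for (j in 1:3) {
    want <- if (i == j) -p2$self_interaction[i]
            else if (cm[i] == cm[j]) 0
            else b2[cm[i], cm[j]]
    expect_equal(A[i, j], want)
  }
})

test_that("drift matches the per-capita formula", {
  p1 <- glv_params(1, 0, 1, matrix(0, 1, 1))
  expect_equal(glv_drift(0, p1), 0)        # absorbing state
  expect_equal(glv_drift(2, p1), 2)        # pure exponential growth

  b <- matrix(c(0, 0, 0.3, 0), 2, 2)       # effect of module 2 on module 1
  p2 <- glv_params(c(1, 0.5), c(0.1, 0.2), c(1, 2), b)
  d <- glv_drift(c(1, 2), p2)
  expect_equal(d[1], 1 * (1 - 0.1 * 1 + 0.3 * 2))  # = 1.5
  expect_error(glv_drift(c(-1, 2), p2), "negative")
})

test_that("one-step log mean follows the first-order discretization", {
  p <- glv_params(0.5, 1e-9, 1, matrix(0, 1, 1))
  expect_equal(step_mean_log(1e8, p, 1e-9), log(1e8), tolerance = 1e-6)
  mu <- step_mean_log(1e8, p, 0.5)
  expect_equal(mu, log(1e8) + 0.5 * (0.5 - 1e-9 * 1e8))
  expect_equal(exp(mu), 1.2214e8, tolerance = 1e-4)
  expect_error(step_mean_log(1e8, p, 0), "delta")

  # active perturbation with gamma = -1 cancels growth entirely
  pp <- glv_params(2, 1e-9, 1, matrix(0, 1, 1),
                   pert_effects = matrix(-1, 1, 1),
                   pert_indicators = matrix(1, 1, 1))
  mu_p <- step_mean_log(1e8, pp, 0.5, pert_on = 1)
  expect_equal(mu_p, log(1e8) + 0.5 * (-1e-9 * 1e8))
})

test_that("drift and step mean agree to first order (Richardson check)", {
  set.seed(7)
  b <- matrix(c(0, -2e-10, 3e-10, 0), 2, 2)
  p <- glv_params(c(1, 0.7), c(1e-9, 2e-9), c(1, 2), b)
  x <- c(2e8, 5e8)
  d <- glv_drift(x, p) / x                 # per-capita drift
  for (delta in c(1e-2, 1e-3)) {
    mu <- step_mean_log(x, p, delta)
    expect_equal((mu - log(x)) / delta, d, tolerance = 1e-6)
  }
})

test_that("module-indexed drift equals matrix-algebra drift", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 5
    b <- matrix(rnorm(9, 0, 2e-10), 3, 3); diag(b) <- 0
    mods <- sample(rep(1:3, length.out = n))
    p <- glv_params(runif(n, 0.5, 1.5), runif(n, 5e-10, 2e-9), mods, b)
    x <- runif(n, 1e7, 1e9)
    A <- expand_to_taxa(p)
    expect_equal(glv_drift(x, p), x * (p$growth + as.numeric(A %*% x)))
  }
})

test_that("forward simulation reaches the logistic fixed point", {
  p <- glv_params(1, 1e-9, 1, matrix(0, 1, 1))
  sim <- forward_simulate(p, 1e5, t_grid = c(0, 30), floor = 1)
  expect_equal(sim$x[1, 2], 1e9, tolerance = 1e-3)
  expect_false(sim$divergent)

  # refinement invariance on the same logistic
  fine <- forward_simulate(p, 1e5, t_grid = c(0, 30), floor = 1, dt = 0.002)
  expect_equal(sim$x[1, 2], fine$x[1, 2], tolerance = 1e-3)
})

test_that("simulation respects the floor, the cap and the seed", {
  p <- glv_params(1e-9, 0, 1, matrix(0, 1, 1))   # ~zero growth
  sim <- forward_simulate(p, 2e5, t_grid = 0:5, floor = 1e5)
  expect_equal(sim$x[1, ], rep(2e5, 6), tolerance = 1e-6)
  sim2 <- forward_simulate(p, 1e4, t_grid = 0:5, floor = 1e5)
  expect_true(all(sim2$x >= 1e5))

  ps <- glv_params(1, 1e-9, 1, matrix(0, 1, 1), process_var = 0.5)
  set.seed(9); a <- forward_simulate(ps, 1e7, 0:10, mode = "stochastic")
  set.seed(9); b <- forward_simulate(ps, 1e7, 0:10, mode = "stochastic")
  expect_identical(a$x, b$x)
  expect_gt(stats::sd(log(a$x[1, ])), 0)

  # explosive growth is flagged divergent, not an error
  pe <- glv_params(80, 0, 1, matrix(0, 1, 1))
  expect_true(forward_simulate(pe, 1e10, 0:10, cap = 1e15)$divergent)
})

test_that("interaction parameter counts follow the ordered-pair formula", {
  expect_equal(count_interaction_parameters(141), 19740)
  expect_equal(count_interaction_parameters(17), 272)
  expect_equal(count_interaction_parameters(1), 0)
})

test_that("expected module count under the DP prior", {
  expect_equal(expected_module_count(1, 141), log(142))
  expect_equal(expected_module_count(1e6, 1), 1, tolerance = 1e-5)
  grid <- vapply(1:200, function(n) expected_module_count(2, n), numeric(1))
  expect_true(all(diff(grid) > 0))
})
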