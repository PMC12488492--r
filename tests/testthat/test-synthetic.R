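test_that("ground-truth generator is seeded, screened and pass-through", {
  t1 <- make_ground_truth(n_taxa = 8, n_modules = 3, density = 0.3, seed = 5)
  t2 <- make_ground_truth(n_taxa = 8, n_modules = 3, density = 0.3, seed = 5)
  expect_identical(t1, t2)

  # density 0: diagonal-only system reaches carrying capacity
  t0 <- make_ground_truth(n_taxa = 4, n_modules = 2, density = 0, seed = 6)
  expect_true(all(t0$interaction_indicators == 0))
  sim <- forward_simulate(t0, x0 = rep(1e6, 4), t_grid = c(0, 40), floor = 1)
  expect_equal(sim$x[, 2], t0$growth / t0$self_interaction, tolerance = 0.01)

  # pass-through of an external system
  ext <- glv_params(c(1, 1), c(1e-9, 1e-9), 1:2, matrix(0, 2, 2))
  expect_identical(make_ground_truth(from_params = ext), ext)

  # min_edges screen guarantees structure at positive density
  tmin <- make_ground_truth(n_taxa = 6, n_modules = 3, density = 0.3,
                            seed = 7, min_edges = 2)
  expect_gte(sum(tmin$interaction_indicators), 2)
})

test_that("initial-condition sampling matches its lognormal moments", {
  x <- sample_initial_conditions(5, meanlog = rep(20, 3), sdlog = rep(0, 3))
  expect_true(all(x == exp(20)))

  set.seed(8)
  big <- sample_initial_conditions(1e4, meanlog = 20, sdlog = 0.5)
  expect_equal(mean(log(big)), 20, tolerance = 0.02)
  expect_equal(stats::sd(log(big)), 0.5, tolerance = 0.02)

  draws <- lapply(1:10, function(s) {
    sample_initial_conditions(2, meanlog = rep(20, 3), sdlog = rep(0.5, 3),
                              seed = s)
  })
  expect_equal(length(unique(vapply(draws, function(m) m[1, 1],
                                    numeric(1)))), 10)
})

test_that("simulated cohorts concentrate on the latent composition", {
  truth <- make_ground_truth(n_taxa = 5, n_modules = 2, density = 0,
                             seed = 9)
  x0 <- matrix(truth$growth / truth$self_interaction, 5, 1)  # at equilibrium
  study <- simulate_cohort(truth, times = 0:3, x0 = x0, d0 = 0, d1 = 1e-9,
                           qpcr_sdlog = 1e-4, depth = 1e7, depth_sdlog = 0,
                           seed = 10)
  rel_obs <- relative_abundances(study)$S1
  rel_true <- x0[, 1] / sum(x0)
  expect_true(all(abs(rel_obs - rel_true) / rel_true < 0.01))
  # realized read depths are recorded as the column sums
  expect_equal(unname(read_depth(study)$S1), unname(colSums(study$counts$S1)))

  s1 <- simulate_cohort(truth, times = 0:3, x0 = x0, seed = 42)
  s2 <- simulate_cohort(truth, times = 0:3, x0 = x0, seed = 42)
  expect_identical(s1, s2)
})

test_that("downsampling keeps the first point and perturbation onsets", {
  truth <- make_ground_truth(n_taxa = 3, n_modules = 1, density = 0,
                             seed = 11)
  pert <- data.frame(name = "abx", start = 30.2, end = 37)
  tt <- seq(0, 75, by = 1)   # 76 timepoints
  x0 <- matrix(rep(1e8, 3), 3, 2)
  study <- simulate_cohort(truth, times = tt, x0 = x0,
                           perturbations = pert, seed = 12)
  expect_identical(downsample_timepoints(study, 1), study)
  half <- downsample_timepoints(study, 1 / 2)
  expect_equal(length(half$times$S1), 38)
  for (fr in c(3 / 4, 1 / 2, 1 / 4)) {
    ds <- downsample_timepoints(study, fr)
    expect_equal(ds$times$S1[1], 0)
    expect_true(31 %in% ds$times$S1)  # first timepoint inside the window
    expect_equal(length(ds$times$S1), ceiling(fr * 76))
  }
  expect_error(downsample_timepoints(study, 0.6), "fraction")
})

test_that("ten-taxon benchmark follows the challenge design", {
  bm <- ten_taxon_benchmark(seed = 2, n_replicates = 3)
  study <- bm$study
  expect_equal(nrow(study$taxa), 10)
  expect_equal(length(study$subjects), 3)
  for (s in study$subjects) {
    expect_equal(study$times[[s]], 1:30)
    pre <- study$counts[[s]][10, as.character(1:9)]
    expect_true(all(pre == 0))
    expect_gt(sum(study$counts[[s]][10, as.character(15:30)]), 0)
  }

  # Dirichlet-multinomial counts are overdispersed vs multinomial at the
  # same mean composition
  set.seed(13)
  rel <- c(0.5, 0.3, 0.2)
  dm <- replicate(2000, {
    g <- stats::rgamma(3, 300 * rel); p <- g / sum(g)
    stats::rmultinom(1, 1000, p)[1, 1]
  })
  mn <- replicate(2000, stats::rmultinom(1, 1000, rel)[1, 1])
  expect_gt(stats::var(dm) / stats::var(mn), 1.2)
})

test_that("AUC rank formula equals brute-force pair counting", {
  set.seed(14)
  for (rep in 1:5) {
    scores <- round(stats::runif(20), 2)   # include ties
    labels <- stats::rbinom(20, 1, 0.4)
    if (sum(labels) %in% c(0, 20)) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc_roc(scores, labels), brute)
  }
  expect_true(is.na(auc_roc(1:5, rep(1, 5))))
})

test_that("recovery metrics are exact for a perfect posterior and null for
           shuffled scores", {
  truth <- make_ground_truth(n_taxa = 6, n_modules = 3, density = 0.5,
                             seed = 15, min_edges = 2)
  A <- expand_to_taxa(truth)
  st <- delta_store(A, growth = truth$growth, modules = truth$modules,
                    G = 4)
  m <- recovery_metrics(st, truth)
  expect_equal(m$interaction_auc, 1)
  expect_equal(m$cocluster_auc, 1)
  expect_gt(m$strength_spearman, 0.99)

  # random inclusion probabilities give chance-level AUC
  set.seed(16)
  aucs <- replicate(100, {
    stn <- st
    shuf <- array(stats::runif(36), c(6, 6, 1))[, , rep(1, 4)]
    stn$interaction_indicators <- array(shuf, c(6, 6, 4))
    recovery_metrics(stn, truth)$interaction_auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})
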