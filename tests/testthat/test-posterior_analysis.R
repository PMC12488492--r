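test_that("co-clustering probabilities count shared-module samples", {
  st <- delta_store(diag(-1e-9, 3), modules = c(1, 1, 2), G = 2)
  cc <- cocluster_matrix(st)
  expect_equal(unname(cc[1, 2]), 1)
  expect_equal(unname(cc[1, 3]), 0)
  expect_equal(unname(diag(cc)), rep(1, 3))

  st$modules[2, ] <- c(1, 2, 3)     # together in one sample, apart in other
  cc2 <- cocluster_matrix(st)
  expect_equal(unname(cc2[1, 2]), 0.5)

  # symmetry and unit diagonal on random stores
  set.seed(1)
  st$modules <- matrix(sample(3, 6, replace = TRUE), 2, 3)
  cc3 <- cocluster_matrix(st)
  expect_equal(cc3, t(cc3))
  expect_true(all(diag(cc3) == 1))
})

test_that("consensus modules cut the co-clustering tree at the median", {
  blocks <- kronecker(diag(3), matrix(1, 2, 2))
  part <- consensus_modules(blocks, k = 3)
  expect_equal(length(unique(part)), 3)
  expect_true(all(part[1] == part[2], part[3] == part[4], part[5] == part[6]))

  eye <- diag(4)
  expect_equal(sort(consensus_modules(eye, k = 4)), 1:4)
  expect_error(consensus_modules(eye, k = 5), "more modules")

  # noisy two-block matrix
  set.seed(2)
  noisy <- matrix(0.1, 6, 6)
  noisy[1:3, 1:3] <- 0.9; noisy[4:6, 4:6] <- 0.9; diag(noisy) <- 1
  p2 <- consensus_modules(noisy, k = 2)
  expect_equal(length(unique(p2[1:3])), 1)
  expect_equal(length(unique(p2[4:6])), 1)
  expect_false(p2[1] == p2[4])

  # median count comes from the store, rounded half-up
  st <- delta_store(diag(-1e-9, 4), modules = c(1, 1, 2, 2), G = 2)
  st$n_modules <- c(2L, 3L)   # median 2.5 -> 3
  cc <- cocluster_matrix(st)
  expect_equal(length(unique(consensus_modules(cc, st))), 3)

  # invariance to taxon reordering (up to label permutation)
  perm <- c(4, 1, 6, 3, 2, 5)
  pp <- consensus_modules(noisy[perm, perm], k = 2)
  expect_equal(outer(pp, pp, `==`),
               outer(p2[perm], p2[perm], `==`))
})

test_that("Bayes factors follow the posterior/prior odds ratio", {
  expect_equal(as.numeric(bayes_factor(0.5, 0.5)), 1)
  expect_equal(as.numeric(bayes_factor(0.9, 0.5)), 9)
  expect_equal(as.character(bf_tier(150)), "decisive")
  expect_equal(as.character(bf_tier(15)), "strong")
  expect_equal(as.character(bf_tier(5)), "substantial")
  expect_equal(as.character(bf_tier(1)), "none")
  # degenerate frequencies get the half-sample correction
  bf1 <- bayes_factor(1, 0.5, n_samples = 100)
  expect_true(is.finite(bf1))
  expect_equal(as.numeric(bf1), (1 - 1 / 200) / (1 / 200))
  expect_true(attr(bf1, "corrected"))
  expect_error(bayes_factor(0.5, 0), "prior")
  # bf(p, p) = 1 across the unit interval
  for (p in c(0.01, 0.2, 0.5, 0.77, 0.99)) {
    expect_equal(as.numeric(bayes_factor(p, p)), 1)
  }
})

test_that("network extraction respects thresholds, signs and nesting", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 4e-10      # taxon 1 promotes taxon 2, the only edge
  st <- delta_store(A - diag(1e-9, 3), modules = 1:3, G = 300)
  st$config <- inference_config(sparsity_prior = "noninformative")
  net <- extract_network(st, bf_threshold = 100)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, 1)
  expect_equal(net$edges$target, 2)
  expect_equal(net$edges$sign, 1)
  expect_equal(net$edges$strength, 4e-10)
  expect_false(net$edges$straddles_zero)

  expect_equal(nrow(extract_network(st, bf_threshold = Inf)$edges), 0)

  # raising the threshold never adds edges
  set.seed(3)
  inc <- matrix(stats::runif(9), 3, 3); diag(inc) <- 0
  A2 <- matrix(stats::rnorm(9, 0, 1e-10), 3, 3)
  stn <- delta_store(A2 - diag(1e-9, 3), modules = 1:3, G = 100,
                     inclusion = inc)
  stn$config <- inference_config(sparsity_prior = "noninformative")
  sizes <- vapply(c(10^0.5, 10, 100), function(th) {
    nrow(extract_network(stn, th)$edges)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # mixed module identities direct the user to fixed-cluster mode
  stm <- delta_store(A - diag(1e-9, 3), modules = 1:3, G = 2)
  stm$modules[2, ] <- c(1, 1, 2)
  expect_error(extract_network(stm), "fixed-cluster")
})

test_that("adjacency and GraphML export reflect the edge table", {
  A <- matrix(0, 3, 3); A[2, 1] <- 4e-10; A[1, 3] <- -2e-10
  st <- delta_store(A - diag(1e-9, 3), modules = 1:3, G = 10)
  st$config <- inference_config(sparsity_prior = "noninformative")
  net <- extract_network(st, bf_threshold = 10)
  adj <- network_adjacency(net, "sign")
  expect_equal(adj[2, 1], 1)
  expect_equal(adj[1, 3], -1)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path, keystoneness = c(0.1, -0.2, 0))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), nrow(net$edges))
})

test_that("point estimates apply the 0.5 indicator rule inclusively", {
  A <- matrix(0, 2, 2); A[1, 2] <- 3e-10
  st <- delta_store(A - diag(1e-9, 2), modules = 1:2, G = 10)
  # inclusion frequency exactly 0.5 -> zero
  st$interaction_indicators[1, 2, ] <- rep(c(0, 1), 5)
  pe <- point_estimate_params(st)
  expect_equal(pe$interactions[1, 2], 0)
  # inclusion 1 -> median of samples
  st$interaction_indicators[1, 2, ] <- 1
  st$interactions[1, 2, ] <- seq(1e-10, 3e-10, length.out = 10)
  pe2 <- point_estimate_params(st)
  expect_equal(pe2$interactions[1, 2],
               stats::median(seq(1e-10, 3e-10, length.out = 10)))
  # delta posterior round-trips
  expect_equal(pe2$growth, rep(1, 2))
  expect_equal(pe2$self_interaction, rep(1e-9, 2))
})

test_that("posterior summary table has medians and 95% intervals", {
  st <- delta_store(diag(-1e-9, 2), G = 5)
  st$growth <- matrix(rep(1:5, 2), 5, 2)
  tab <- summarize_posterior(st)
  row <- tab[tab$variable == "growth[T1]", ]
  expect_equal(row$median, 3)
  expect_true(row$lo2.5 <= 1.5 && row$hi97.5 >= 4.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  summarize_posterior(st, path)
  expect_true(file.exists(path))
})
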