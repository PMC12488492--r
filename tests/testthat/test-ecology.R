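test_that("right-half-plane eigenvalue counts match closed forms", {
  for (k in c(0.1, 1, 5, 50)) {
    expect_equal(stability_count(matrix(c(-1, -k, k, -1), 2, 2)), 0)
  }
  expect_equal(stability_count(matrix(c(-1, 2, 2, -1), 2, 2)), 1)
  expect_equal(stability_count(diag(c(-1, -2, -3))), 0)
  expect_error(stability_count(matrix(c(NA, 1, 1, 1), 2, 2)), "non-finite")
  # partition identity: counts over the three half-plane classes sum to n
  set.seed(1)
  for (rep in 1:5) {
    A <- matrix(rnorm(25), 5, 5)
    ev <- eigen(A, only.values = TRUE)$values
    expect_equal(stability_count(A) + sum(Re(ev) < 0) + sum(Re(ev) == 0), 5)
  }
})

test_that("in-degree-preserving permutation keeps rows and diagonal", {
  set.seed(2)
  A <- matrix(rnorm(36), 6, 6)
  P <- permute_in_degree(A)
  expect_equal(diag(P), diag(A))
  for (i in 1:6) {
    expect_equal(sort(P[i, -i]), sort(A[i, -i]))
  }
  # uniformity over the 2 possible permutations per row for n = 3
  A3 <- matrix(1:9, 3, 3)
  hits <- replicate(4000, permute_in_degree(A3)[1, 2] == A3[1, 2])
  expect_equal(mean(hits), 0.5, tolerance = 3 * 0.5 / sqrt(4000))
})

test_that("cycle census matches the worked two-cycle example", {
  # edges 1->2 (+), 2->1 (+), 2->3 (-), 3->2 (-); A[target, source]
  A <- matrix(0, 3, 3)
  A[2, 1] <- 1; A[1, 2] <- 1; A[3, 2] <- -1; A[2, 3] <- -1
  cen <- cycle_census(A)
  expect_equal(unname(cen$two[["++"]]), 1)
  expect_equal(unname(cen$two[["--"]]), 1)
  expect_equal(unname(cen$two[["+-"]]), 0)
  expect_equal(mcr(cen), 1)

  chain <- matrix(0, 3, 3); chain[2, 1] <- 1; chain[3, 2] <- 1
  cen2 <- cycle_census(chain)
  expect_equal(sum(cen2$two) + sum(cen2$three), 0)
})

test_that("cycle census equals an independent brute-force enumeration", {
  set.seed(3)
  for (n in 3:5) {
    for (rep in 1:20) {
      A <- random_signed_digraph(n, p = 0.5)
      got <- cycle_census(A)
      want <- brute_cycles(A)
      expect_equal(got$two, want$two)
      expect_equal(got$three, want$three)
    }
  }
})

test_that("MCR division conventions", {
  mk <- function(pp, mm) {
    structure(list(two = c("++" = pp, "--" = mm, "+-" = 0),
                   three = c("+++" = 0, "++-" = 0, "+--" = 0, "---" = 0),
                   n_edges = 2 * (pp + mm)), class = "cycle_census")
  }
  expect_equal(mcr(mk(0, 2)), 0)
  expect_equal(mcr(mk(2, 0)), Inf)
  expect_true(is.na(mcr(mk(0, 0))))
})

test_that("permutation p-values use the add-one convention", {
  A <- matrix(rnorm(25), 5, 5)
  const <- null_significance(1, A, function(m) 1, n_perm = 200)
  expect_equal(const$p, 1)
  far <- null_significance(1e9, A, function(m) sum(m), n_perm = 999,
                           tail = "greater")
  expect_equal(far$p, 1 / 1000)
  expect_error(null_significance(1, A, sum, n_perm = 10), "at least 100")
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(4)
  stat <- function(m) stability_count(m)
  ps <- replicate(60, {
    A <- matrix(rnorm(25, 0, 0.6), 5, 5); diag(A) <- -1
    A <- permute_in_degree(A)    # draw the observed matrix from the null
    null_significance(stat(A), A, stat, n_perm = 150, tail = "greater")$p
  })
  # the statistic is discrete, so the p-value distribution is lumpy and
  # conservative; check validity and the absence of anti-conservatism
  expect_true(all(ps > 0 & ps <= 1))
  expect_lte(mean(ps <= 0.2), 0.3)
  expect_gt(mean(ps), 0.3)
})

test_that("keystoneness of a decoupled community vanishes", {
  A <- diag(c(-1e-9, -2e-9, -1e-9))
  st <- delta_store(A, growth = c(1, 1.4, 0.8), modules = c(1, 1, 2))
  k <- keystoneness(st, module = 2, partition = c(1, 1, 2),
                    x0 = c(1e9, 7e8, 8e8))
  expect_equal(k$k, 0, tolerance = 1e-9)
})

test_that("two-taxon toy keystoneness equals log10(2)", {
  b <- matrix(0, 2, 2); b[2, 1] <- 1e-9     # module 1 promotes taxon 2
  A <- b; diag(A) <- -1e-9
  st <- delta_store(A, growth = c(1, 1), modules = c(1, 2))
  k <- keystoneness(st, module = 1, partition = c(1, 2), x0 = c(1e9, 2e9))
  expect_equal(k$k, log10(2), tolerance = 1e-3)

  # in the weak-interaction regime flipping b's sign flips k's sign at
  # matching magnitude (the equilibrium shift is linear in b there)
  for (s in c(1, -1)) {
    bw <- matrix(0, 2, 2); bw[2, 1] <- s * 2e-11
    Aw <- bw; diag(Aw) <- -1e-9
    stw <- delta_store(Aw, growth = c(1, 1), modules = c(1, 2))
    kw <- keystoneness(stw, module = 1, partition = c(1, 2),
                       x0 = c(1e9, 1e9))
    if (s == 1) kplus <- kw$k else kminus <- kw$k
  }
  expect_gt(kplus, 0)
  expect_lt(kminus, 0)
  expect_equal(abs(kminus), abs(kplus), tolerance = 0.05)

  expect_error(keystoneness(st, module = 1, partition = c(1, 1)),
               "whole community")
})

test_that("hypergeometric enrichment with BH correction", {
  # N = 10 assigned taxa, one group of 3, one module of 3 holding all of
  # them: p = 1 / choose(10, 3)
  taxonomy <- data.frame(phylum = c(rep("Bacteroidetes", 3),
                                    rep("Firmicutes", 7)))
  partition <- c(1, 1, 1, rep(2, 7))
  tab <- enrichment(partition, taxonomy, "phylum")
  hit <- tab[tab$module == 1 & tab$group == "Bacteroidetes", ]
  expect_equal(hit$p, 1 / choose(10, 3))

  # a module containing every taxon is never enriched
  tab2 <- enrichment(rep(1, 10), taxonomy, "phylum")
  expect_true(all(tab2$p == 1))

  # BH on the worked example
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))

  # unassigned taxa are excluded
  taxonomy$phylum[1] <- NA
  tab3 <- enrichment(partition, taxonomy, "phylum")
  expect_true(all(tab3$total == 9))
})

test_that("stability profile returns observed and permuted counts", {
  set.seed(5)
  A <- matrix(0, 3, 3); A[2, 1] <- 4e-10
  st <- delta_store(A - diag(1e-9, 3), modules = 1:3, G = 4)
  prof <- stability_profile(st)
  expect_equal(nrow(prof), 4)
  expect_true(all(prof$rhp == 0))
  expect_true(all(prof$rhp_null >= 0))
})
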