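#' Taxon-level interaction matrix of one posterior sample
#'
#' Off-diagonal entries are the indicator-gated module interactions mapped
#' to taxon level; the diagonal holds the negative self-interactions.
#'
#' @param store a `glv_posterior`.
#' @param g sample index.
#' @return n x n matrix (entry (i, j) = signed effect of taxon j on i).
#' @export
posterior_interaction_matrix <- function(store, g) {
  A <- store$interactions[, , g]
  diag(A) <- -store$self_interaction[g, ]
  A
}

#' Count of right-half-plane eigenvalues
#'
#' The number of eigenvalues of the interaction matrix with strictly
#' positive real part; zero means the interaction structure admits a
#' locally stable community.
#'
#' @param A square real interaction matrix.
#' @return integer count.
#' @export
stability_count <- function(A) {
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop("interaction matrix has non-finite entries")
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  ev <- eigen(A, only.values = TRUE)$values
  sum(Re(ev) > 0)
}

#' In-degree-preserving permutation of an interaction matrix
#'
#' Permutes the off-diagonal entries within each row uniformly at random
#' and leaves the diagonal untouched, so the total edge count and every
#' node's incoming-edge multiset are preserved while edge sources are
#' randomized. Apply at module level for module-structured matrices.
#'
#' @param A square matrix.
#' @return permuted matrix (uses the current RNG stream).
#' @export
permute_in_degree <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  for (i in seq_len(n)) {
    off <- setdiff(seq_len(n), i)
    A[i, off] <- A[i, sample(off)]
  }
  A
}

#' Stability profile over posterior samples
#'
#' For each posterior sample, the number of right-half-plane eigenvalues
#' of the taxon-level interaction matrix, optionally compared with one
#' in-degree-preserving permutation per sample (permuted at module level
#' when the partition is fixed across samples, then expanded to taxon
#' level).
#'
#' @param store a `glv_posterior`.
#' @param permuted also compute a permuted-null count per sample.
#' @param samples subset of sample indices (default all).
#' @return data frame with `sample`, `rhp` and (optionally) `rhp_null`.
#' @export
stability_profile <- function(store, permuted = TRUE, samples = NULL) {
  if (is.null(samples)) samples <- seq_len(store$n_samples)
  fixed <- nrow(unique(store$modules)) == 1
  part <- store$modules[1, ]
  out <- data.frame(sample = samples, rhp = NA_integer_)
  if (permuted) out$rhp_null <- NA_integer_
  for (u in seq_along(samples)) {
    g <- samples[u]
    A <- posterior_interaction_matrix(store, g)
    out$rhp[u] <- stability_count(A)
    if (!permuted) next
    if (fixed) {
      M <- max(part)
      reps <- vapply(seq_len(M), function(m) which(part == m)[1], integer(1))
      B <- matrix(store$interactions[reps, reps, g], M, M)
      B <- permute_in_degree(B)
      Ap <- B[part, part]
      Ap[outer(part, part, `==`)] <- 0
      diag(Ap) <- -store$self_interaction[g, ]
    } else {
      Ap <- permute_in_degree(A)
    }
    out$rhp_null[u] <- stability_count(Ap)
  }
  out
}

#' Census of signed 2- and 3-cycles in a directed network
#'
#' Counts simple directed cycles of length 2 and 3 in a signed adjacency
#' matrix (entry (i, j) nonzero means an edge from j to i with that sign),
#' classified by the multiset of edge signs. Cycles are rotation-invariant
#' (each directed cycle counted once); the two orientations of a triangle
#' are distinct cycles. Self-loops (diagonal) are ignored.
#'
#' @param A signed adjacency matrix.
#' @param max_len 2 or 3.
#' @return a `cycle_census`: list with `two` (counts for "++", "--", "+-"),
#'   `three` (counts by sign multiset) and `n_edges`.
#' @export
cycle_census <- function(A, max_len = 3) {
  stopifnot(max_len %in% c(2, 3))
  A <- as.matrix(A)
  diag(A) <- 0
  n <- nrow(A)
  two <- c("++" = 0, "--" = 0, "+-" = 0)
  three <- c("+++" = 0, "++-" = 0, "+--" = 0, "---" = 0)
  sgn <- function(v) paste(sort(ifelse(v > 0, "+", "-"),
                                decreasing = TRUE), collapse = "")
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (A[i, j] != 0 && A[j, i] != 0) {
          key <- sgn(c(A[i, j], A[j, i]))
          two[key] <- two[key] + 1
        }
      }
    }
  }
  if (max_len >= 3 && n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          # orientation i -> j -> k -> i: edges stored as A[target, source]
          if (A[j, i] != 0 && A[k, j] != 0 && A[i, k] != 0) {
            key <- sgn(c(A[j, i], A[k, j], A[i, k]))
            three[key] <- three[key] + 1
          }
          # reverse orientation i -> k -> j -> i
          if (A[k, i] != 0 && A[j, k] != 0 && A[i, j] != 0) {
            key <- sgn(c(A[k, i], A[j, k], A[i, j]))
            three[key] <- three[key] + 1
          }
        }
      }
    }
  }
  structure(list(two = two, three = three,
                 n_edges = sum(A != 0)), class = "cycle_census")
}

#' Mutualism-to-competition ratio
#'
#' Ratio of (+,+) to (-,-) two-cycles. Infinite when there is mutualism but
#' no competition; NA (undefined) when there is neither.
#'
#' @param census a `cycle_census`.
#' @return numeric ratio (possibly `Inf` or `NA`).
#' @export
mcr <- function(census) {
  mut <- census$two[["++"]]; comp <- census$two[["--"]]
  if (comp == 0) {
    if (mut == 0) return(NA_real_)
    return(Inf)
  }
  mut / comp
}

#' Permutation p-value for a network statistic
#'
#' Compares an observed statistic against its distribution over
#' in-degree-preserving permutations of the interaction matrix, with the
#' add-one convention `p = (1 + #{at least as extreme}) / (1 + n_perm)`.
#'
#' @param observed observed statistic value.
#' @param A matrix to permute.
#' @param stat_fn function mapping a matrix to the statistic.
#' @param n_perm number of permutations (>= 100).
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @return list with `p`, the null draws, and the observed value.
#' @export
null_significance <- function(observed, A, stat_fn, n_perm = 1000,
                              tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (n_perm < 100) stop("n_perm must be at least 100")
  null <- vapply(seq_len(n_perm),
                 function(u) stat_fn(permute_in_degree(A)), numeric(1))
  extreme <- switch(tail,
    greater = sum(null >= observed),
    less = sum(null <= observed),
    two.sided = {
      ctr <- stats::median(null)
      sum(abs(null - ctr) >= abs(observed - ctr))
    })
  list(p = (1 + extreme) / (1 + n_perm), null = null, observed = observed)
}

#' Module keystoneness
#'
#' Removes all taxa of module `m`, forward-simulates the remaining
#' community and the full community from the same initial state over
#' `horizon` days per posterior sample, takes final states as the mean
#' over the last `window` days, and scores
#' `k(m) = -mean_g[ mean_{i not in m}( log10(x_removed + eps)
#'  - log10(x_full + eps) ) ]`,
#' so positive keystoneness means the module props up the rest of the
#' community. Simulations are deterministic (no process noise) with the
#' detection floor applied.
#'
#' @param store a `glv_posterior` (fixed-cluster mode recommended).
#' @param module module label to remove.
#' @param partition module partition (defaults to the store's first
#'   sample).
#' @param x0 initial abundances; defaults to the posterior latent state at
#'   the last pre-perturbation observed timepoint (averaged over subjects)
#'   per stored-latent sample.
#' @param horizon simulation length in days.
#' @param window averaging window for the final state, in days (12 h =
#'   0.5).
#' @param eps offset inside the log10 (default 1e5, the detection floor).
#' @param floor simulation clamp (cfu/g).
#' @param dt simulation step (days).
#' @param samples posterior sample indices to use (default: those with
#'   stored latents, or all if `x0` is supplied).
#' @return list with `k` (the keystoneness), and per-sample contributions.
#' @export
keystoneness <- function(store, module, partition = NULL, x0 = NULL,
                         horizon = 100, window = 0.5, eps = 1e5,
                         floor = 1e5, dt = 0.01, samples = NULL) {
  if (is.null(partition)) partition <- store$modules[1, ]
  inside <- which(partition == module)
  outside <- which(partition != module)
  if (!length(inside)) stop("module ", module, " has no members")
  if (!length(outside)) stop("cannot remove the whole community")

  lat_stride <- max(store$config$latent_every, 1)
  if (is.null(samples)) {
    samples <- if (is.null(x0) && length(store$latents)) {
      seq(1, by = lat_stride, length.out = length(store$latents))
    } else seq_len(store$n_samples)
  }
  t_grid <- c(0, seq(horizon - window, horizon, by = dt))
  P <- length(store$pert_names)
  contrib <- numeric(0)
  for (u in seq_along(samples)) {
    g <- samples[u]
    xg <- if (!is.null(x0)) x0 else initial_state_from_latents(store, u)
    a1 <- store$growth[g, ]
    A <- posterior_interaction_matrix(store, g)
    GT <- if (P > 0) t(store$pert_effects[, , g] *
                       store$pert_indicators[, , g]) else matrix(0, 1, length(a1))
    full <- simulate_taxon_level(a1, A, GT, xg, t_grid, sigma_w2 = 0,
                                 floor = floor, dt = dt)
    red <- simulate_taxon_level(a1[-inside],
                                A[-inside, -inside, drop = FALSE],
                                GT[, -inside, drop = FALSE],
                                xg[-inside], t_grid, sigma_w2 = 0,
                                floor = floor, dt = dt)
    win <- 2:ncol(full$x)
    xf <- rowMeans(full$x[, win, drop = FALSE])
    xr <- rowMeans(red$x[, win, drop = FALSE])
    pos_in_red <- match(outside, setdiff(seq_along(a1), inside))
    contrib[u] <- mean(log10(xr[pos_in_red] + eps) -
                       log10(xf[outside] + eps))
  }
  list(k = -mean(contrib), per_sample = -contrib, module = module,
       n_samples = length(samples))
}

# mean over subjects of the stored latent state at the last
# pre-perturbation observed timepoint
initial_state_from_latents <- function(store, lat_idx) {
  if (!length(store$latents)) {
    stop("no stored latent trajectories; supply x0")
  }
  lat <- store$latents[[min(lat_idx, length(store$latents))]]
  first_pert <- if (!is.null(store$perturbations)) {
    min(store$perturbations$start)
  } else Inf
  xs <- lapply(seq_along(store$subjects), function(s) {
    tt <- store$times[[store$subjects[s]]]
    k <- if (any(tt < first_pert)) max(which(tt < first_pert)) else length(tt)
    exp(lat[[s]][, k])
  })
  Reduce(`+`, xs) / length(xs)
}

#' Taxonomic enrichment of modules
#'
#' One-sided hypergeometric test of over-representation of each taxonomic
#' group within each module (P(X >= k) with N taxa total, M in the group,
#' n in the module, k in both), followed by Benjamini-Hochberg correction
#' across all tests at the level. Taxa without a label at the level are
#' excluded.
#'
#' @param partition integer module labels per taxon.
#' @param taxonomy data frame with one row per taxon and a column per rank.
#' @param level rank column to test (e.g. "phylum", "class", "order",
#'   "family").
#' @return data frame: module, group, overlap, module_size, group_size,
#'   total, p, q.
#' @export
enrichment <- function(partition, taxonomy,
                       level = c("phylum", "class", "order", "family")) {
  level <- match.arg(level, choices = names(taxonomy), several.ok = FALSE)
  labels <- taxonomy[[level]]
  assigned <- !is.na(labels) & labels != ""
  part <- partition[assigned]
  labels <- labels[assigned]
  N <- length(labels)
  rows <- list()
  for (m in sort(unique(part))) {
    nsize <- sum(part == m)
    for (gp in sort(unique(labels))) {
      Mg <- sum(labels == gp)
      k <- sum(part == m & labels == gp)
      p <- stats::phyper(k - 1, Mg, N - Mg, nsize, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, group = gp, overlap = k, module_size = nsize,
        group_size = Mg, total = N, p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
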