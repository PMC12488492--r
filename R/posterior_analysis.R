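#' Posterior co-clustering probability matrix
#'
#' Entry (i, j) is the fraction of posterior samples in which taxa i and j
#' share a module. Symmetric with a unit diagonal.
#'
#' @param store a `glv_posterior`.
#' @return n x n probability matrix.
#' @export
cocluster_matrix <- function(store) {
  cs <- store$modules           # G x n
  G <- nrow(cs); n <- ncol(cs)
  M <- matrix(0, n, n)
  for (g in seq_len(G)) {
    M <- M + outer(cs[g, ], cs[g, ], `==`)
  }
  M <- M / G
  dimnames(M) <- list(store$taxa, store$taxa)
  M
}

#' Consensus module partition
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' `1 - coclustering probability`, cut at the median posterior module count
#' (rounded half-up). Deterministic given the matrix.
#'
#' @param cocluster co-clustering probability matrix.
#' @param store the posterior store the matrix came from (supplies the
#'   median module count), or NULL if `k` is given.
#' @param k optional explicit number of consensus modules.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return integer partition vector (module labels 1..k).
#' @export
consensus_modules <- function(cocluster, store = NULL, k = NULL,
                              linkage = "average") {
  n <- nrow(cocluster)
  if (is.null(k)) {
    if (is.null(store)) stop("supply either a store or k")
    k <- floor(stats::median(store$n_modules) + 0.5)  # round half-up
  }
  if (k > n) stop("requested more modules than taxa")
  hc <- stats::hclust(stats::as.dist(1 - cocluster), method = linkage)
  part <- stats::cutree(hc, k = k)
  as.integer(part)
}

#' Bayes factor for an edge from posterior and prior inclusion
#'
#' `BF = [p/(1-p)] / [p0/(1-p0)]` with `p` the posterior inclusion
#' frequency of the indicator and `p0` its prior inclusion probability.
#' Monte-Carlo-degenerate frequencies of exactly 0 or 1 are shifted by a
#' half-sample continuity correction, `1/(2G)` and `1 - 1/(2G)`, so the BF
#' stays finite and reportable (flagged by the `corrected` attribute).
#'
#' @param posterior_p posterior inclusion frequency in [0, 1].
#' @param prior_p prior inclusion probability in (0, 1).
#' @param n_samples number of posterior samples (for the correction).
#' @return Bayes factor(s), with attribute `corrected`.
#' @export
bayes_factor <- function(posterior_p, prior_p, n_samples = Inf) {
  stopifnot(all(posterior_p >= 0), all(posterior_p <= 1))
  if (any(prior_p <= 0) || any(prior_p >= 1)) {
    stop("prior inclusion probability must be in (0, 1)")
  }
  corrected <- posterior_p %in% c(0, 1) & is.finite(n_samples)
  p <- posterior_p
  p[p == 0 & corrected] <- 1 / (2 * n_samples)
  p[p == 1 & corrected] <- 1 - 1 / (2 * n_samples)
  bf <- (p / (1 - p)) / (prior_p / (1 - prior_p))
  attr(bf, "corrected") <- corrected
  bf
}

#' Evidence tier for a Bayes factor
#'
#' Standard tiers: "substantial" (BF >= 10^0.5), "strong" (BF >= 10),
#' "decisive" (BF >= 100); below 10^0.5 is "none".
#'
#' @param bf Bayes factor(s).
#' @return character vector of tiers.
#' @export
bf_tier <- function(bf) {
  cut(as.numeric(bf), c(-Inf, 10^0.5, 10, 100, Inf),
      labels = c("none", "substantial", "strong", "decisive"),
      right = FALSE)
}

#' Extract the module-level interaction network from a fixed-cluster
#' posterior
#'
#' Edges are module pairs whose interaction indicator reaches the requested
#' Bayes-factor threshold; per-edge sign and strength come from the
#' conditional posterior median (samples where the indicator is on). Edges
#' whose conditional central 95\% interval straddles zero are flagged.
#'
#' @param store a `glv_posterior` from a fixed-cluster (or
#'   module-learning-off) run; mixed module identities across samples are
#'   an error.
#' @param bf_threshold minimum Bayes factor for inclusion (e.g. 10^0.5,
#'   10, 100).
#' @return a `module_network`: list with `nodes` (module sizes and member
#'   taxa) and `edges` (source, target, sign, median strength, BF, tier,
#'   straddles_zero).
#' @export
extract_network <- function(store, bf_threshold = 100) {
  cs <- store$modules
  if (nrow(unique(cs)) != 1) {
    stop("module assignments vary across samples; rerun inference in ",
         "fixed-cluster mode (module_learning = 'fixed') before ",
         "extracting a module network")
  }
  part <- cs[1, ]
  M <- max(part)
  prior_p <- prior_inclusion_probability(store$config)[["interaction"]]
  G <- store$n_samples
  reps <- vapply(seq_len(M), function(m) which(part == m)[1], integer(1))

  edges <- list()
  for (m in seq_len(M)) {
    for (mp in seq_len(M)) {
      if (m == mp) next
      i <- reps[m]; j <- reps[mp]
      zs <- store$interaction_indicators[i, j, ]
      p <- mean(zs)
      bf <- as.numeric(bayes_factor(p, prior_p, G))
      if (bf < bf_threshold) next
      bs <- store$interactions[i, j, zs == 1]
      qs <- stats::quantile(bs, c(0.025, 0.5, 0.975), names = FALSE)
      edges[[length(edges) + 1]] <- data.frame(
        source = mp, target = m,         # effect of mp on m
        sign = sign(qs[2]), strength = qs[2], bayes_factor = bf,
        tier = as.character(bf_tier(bf)),
        straddles_zero = qs[1] < 0 && qs[3] > 0)
    }
  }
  nodes <- data.frame(module = seq_len(M),
                      size = as.integer(table(factor(part, seq_len(M)))))
  nodes$members <- vapply(seq_len(M), function(m) {
    paste(store$taxa[part == m], collapse = ",")
  }, character(1))
  structure(list(nodes = nodes,
                 edges = if (length(edges)) do.call(rbind, edges) else
                   data.frame(source = integer(0), target = integer(0),
                              sign = numeric(0), strength = numeric(0),
                              bayes_factor = numeric(0), tier = character(0),
                              straddles_zero = logical(0)),
                 partition = part, bf_threshold = bf_threshold),
            class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  cat("module_network:", nrow(x$nodes), "modules,", nrow(x$edges),
      "edges at BF >=", x$bf_threshold, "\n")
  invisible(x)
}

#' Signed module-level adjacency matrix of a network
#' @param network a `module_network`.
#' @param what `"sign"` or `"strength"`.
#' @return M x M matrix, entry (m, mp) = effect of module mp on module m.
#' @export
network_adjacency <- function(network, what = c("sign", "strength")) {
  what <- match.arg(what)
  M <- nrow(network$nodes)
  A <- matrix(0, M, M)
  e <- network$edges
  if (nrow(e)) A[cbind(e$target, e$source)] <- e[[what]]
  A
}

#' Export a module network to GraphML
#'
#' Writes a Cytoscape-compatible GraphML file with node attributes (size,
#' members, keystoneness when supplied) and edge attributes (sign,
#' strength, Bayes factor, tier).
#'
#' @param network a `module_network`.
#' @param path output file.
#' @param keystoneness optional per-module keystoneness vector.
#' @return the path, invisibly.
#' @export
write_graphml <- function(network, path, keystoneness = NULL) {
  g <- igraph::make_empty_graph(n = nrow(network$nodes), directed = TRUE)
  igraph::V(g)$name <- paste0("M", network$nodes$module)
  igraph::V(g)$size <- network$nodes$size
  igraph::V(g)$members <- network$nodes$members
  if (!is.null(keystoneness)) igraph::V(g)$keystoneness <- keystoneness
  e <- network$edges
  if (nrow(e)) {
    g <- igraph::add_edges(g, rbind(e$source, e$target))
    igraph::E(g)$sign <- e$sign
    igraph::E(g)$strength <- e$strength
    igraph::E(g)$bayes_factor <- e$bayes_factor
    igraph::E(g)$tier <- e$tier
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Posterior point estimates with the indicator threshold rule
#'
#' Interaction and perturbation coefficients are set to zero when their
#' posterior inclusion frequency is <= `threshold` (default 0.5, boundary
#' inclusive) and to the posterior median otherwise; growth and
#' self-interaction are posterior medians. Module assignment is taken from
#' the modal partition.
#'
#' @param store a `glv_posterior`.
#' @param threshold inclusion-frequency threshold.
#' @return list with taxon-level `growth`, `self_interaction`,
#'   `interactions` (n x n), `pert_effects` (n x P), `process_var`,
#'   `modules`.
#' @export
point_estimate_params <- function(store, threshold = 0.5) {
  n <- length(store$taxa)
  med <- function(m) apply(m, 2, stats::median)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    p <- mean(store$interaction_indicators[i, j, ])
    if (p > threshold) A[i, j] <- stats::median(store$interactions[i, j, ])
  }
  P <- if (!is.null(store$pert_effects)) dim(store$pert_effects)[2] else 0
  Gm <- matrix(0, n, max(P, 0))
  if (P > 0) {
    for (i in seq_len(n)) for (p in seq_len(P)) {
      pp <- mean(store$pert_indicators[i, p, ])
      if (pp > threshold) {
        Gm[i, p] <- stats::median(store$pert_effects[i, p, ])
      }
    }
  }
  part <- store$modules[which.max(
    tabulate(match(apply(store$modules, 1, paste, collapse = ","),
                   unique(apply(store$modules, 1, paste, collapse = ","))))
  ), ]
  list(growth = med(store$growth),
       self_interaction = med(store$self_interaction),
       interactions = A, pert_effects = Gm,
       process_var = stats::median(store$process_var),
       modules = as.integer(part))
}

#' Posterior summary table
#'
#' Median and central 95\% interval for every scalar model variable,
#' written as one row per variable (TSV-friendly).
#'
#' @param store a `glv_posterior`.
#' @param path optional TSV output path.
#' @return data frame of summaries.
#' @export
summarize_posterior <- function(store, path = NULL) {
  qrow <- function(name, draws) {
    q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(variable = name, median = q[2], lo2.5 = q[1], hi97.5 = q[3])
  }
  rows <- list()
  for (i in seq_along(store$taxa)) {
    rows[[length(rows) + 1]] <- qrow(paste0("growth[", store$taxa[i], "]"),
                                     store$growth[, i])
    rows[[length(rows) + 1]] <- qrow(
      paste0("self_interaction[", store$taxa[i], "]"),
      store$self_interaction[, i])
  }
  rows[[length(rows) + 1]] <- qrow("process_var", store$process_var)
  rows[[length(rows) + 1]] <- qrow("concentration", store$concentration)
  rows[[length(rows) + 1]] <- qrow("n_modules", store$n_modules)
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
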