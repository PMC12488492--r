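# shared fixtures built in code

toy_study_paths <- function() {
  dir <- system.file("extdata", "toy_study", package = "glvmod")
  list(taxa = file.path(dir, "taxa.tsv"),
       counts = file.path(dir, "counts.tsv"),
       metadata = file.path(dir, "metadata.tsv"),
       qpcr = file.path(dir, "qpcr.tsv"),
       perturbations = file.path(dir, "perturbations.tsv"))
}

toy_study <- function() {
  p <- toy_study_paths()
  read_study(p$taxa, p$counts, p$metadata, p$qpcr, p$perturbations)
}

# minimal posterior store with G identical samples of an explicit system;
# used to test posterior summaries end to end without running MCMC
delta_store <- function(A, growth = rep(1, nrow(A)), modules = seq_len(nrow(A)),
                        G = 1, inclusion = NULL, config = inference_config()) {
  n <- nrow(A)
  a2 <- -diag(A)
  off <- A
  diag(off) <- 0
  if (is.null(inclusion)) inclusion <- (off != 0) * 1
  structure(list(
    growth = matrix(growth, G, n, byrow = TRUE),
    self_interaction = matrix(a2, G, n, byrow = TRUE),
    modules = matrix(modules, G, n, byrow = TRUE),
    n_modules = rep(max(modules), G),
    process_var = rep(0.01, G), concentration = rep(1, G),
    interactions = array(off, c(n, n, G)),
    interaction_indicators = array(inclusion, c(n, n, G)),
    pert_effects = NULL, pert_indicators = NULL, latents = list(),
    taxa = paste0("T", seq_len(n)), subjects = "S1",
    times = list(S1 = c(0, 1)), pert_names = character(0),
    perturbations = NULL, acceptance = rep(0.4, n),
    config = config, priors = default_priors(), seed = 1, n_samples = G
  ), class = "glv_posterior")
}

# technical-replicate generator for dispersion-fit recovery: even-ish
# common taxa plus planted rare taxa so both constants are identifiable
dispersion_replicates <- function(d0, d1, depth = 1e8, n_spec = 9,
                                  n_rep = 2) {
  rows <- list()
  for (sp in seq_len(n_spec)) {
    common <- stats::rlnorm(14, 0, 1)
    rare <- 10^seq(-7, -5, length.out = 6) * stats::runif(6, 0.5, 2)
    rel <- c(common / sum(common) * (1 - sum(rare)), rare)
    for (r in seq_len(n_rep)) {
      eps <- d0 / rel + d1
      y <- vapply(seq_along(rel), function(i) {
        rnegbin_eps(1, depth * rel[i], eps[i])
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        specimen = sp, replicate = r,
        taxon = paste0("T", seq_along(rel)), count = y)
    }
  }
  do.call(rbind, rows)
}

# independent brute-force census of signed 2-/3-cycles by path walking
# (deliberately different algorithm from cycle_census)
brute_cycles <- function(A) {
  n <- nrow(A)
  diag(A) <- 0
  sgn <- function(v) paste(sort(ifelse(v > 0, "+", "-"),
                                decreasing = TRUE), collapse = "")
  two <- c("++" = 0, "--" = 0, "+-" = 0)
  three <- c("+++" = 0, "++-" = 0, "+--" = 0, "---" = 0)
  # walk all ordered simple cycles and de-duplicate by rotation
  seen2 <- character(0); seen3 <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (A[j, i] != 0 && A[i, j] != 0) {       # i -> j -> i
      key <- paste(sort(c(i, j)), collapse = "-")
      if (!(key %in% seen2)) {
        seen2 <- c(seen2, key)
        two[sgn(c(A[j, i], A[i, j]))] <- two[sgn(c(A[j, i], A[i, j]))] + 1
      }
    }
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (A[j, i] != 0 && A[k, j] != 0 && A[i, k] != 0) {  # i->j->k->i
        rot <- c(i, j, k)
        start <- which.min(rot)
        canon <- paste(rot[((start - 1 + 0:2) %% 3) + 1], collapse = "-")
        if (!(canon %in% seen3)) {
          seen3 <- c(seen3, canon)
          key <- sgn(c(A[j, i], A[k, j], A[i, k]))
          three[key] <- three[key] + 1
        }
      }
    }
  }
  list(two = two, three = three)
}

random_signed_digraph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  off <- which(row(A) != col(A))
  on <- off[stats::runif(length(off)) < p]
  A[on] <- sample(c(-1, 1), length(on), replace = TRUE) *
    stats::runif(length(on), 0.5, 2)
  A
}
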