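#' Abundance-dependent negative-binomial dispersion
#'
#' The sequencing noise model uses a negative binomial whose dispersion
#' grows at low relative abundance: `eps = d0 / rel + d1`. Under the
#' mean-dispersion parameterization used throughout (variance =
#' mean + eps * mean^2), `eps` is the excess-variance coefficient, so
#' low-abundance taxa are the most overdispersed.
#'
#' @param rel relative abundance(s), > 0.
#' @param d0,d1 dispersion constants (>= 0).
#' @return dispersion values.
#' @export
nb_dispersion <- function(rel, d0, d1) {
  if (any(rel <= 0)) stop("relative abundance must be positive")
  d0 / rel + d1
}

# internal: NB log-pmf with mean mu and excess-variance eps
nb_logpmf <- function(y, mu, eps) {
  ifelse(eps < 1e-12,
         stats::dpois(y, mu, log = TRUE),
         stats::dnbinom(y, size = 1 / eps, mu = mu, log = TRUE))
}

#' Negative-binomial sampler under the mean/excess-variance form
#' @param n number of draws.
#' @param mu mean.
#' @param eps excess-variance coefficient (variance = mu + eps * mu^2).
#' @return integer draws.
#' @export
rnegbin_eps <- function(n, mu, eps) {
  if (eps < 1e-12) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / eps, mu = mu)
}

#' Log-likelihood of sequencing counts given latent abundances
#'
#' Counts for taxon i are NegBin with mean `phi = r * x_i / sum(x)` and
#' dispersion `eps(x_i / sum(x))`. Only relative abundances enter, so the
#' result is invariant to rescaling all latent abundances. Relative
#' abundances are floored at `rel_floor` inside the dispersion to keep it
#' finite for numerically extinct states.
#'
#' @param y count vector (length n).
#' @param x latent abundances (length n, > 0 somewhere).
#' @param r total reads for the sample.
#' @param d list or vector with `d0`, `d1`.
#' @param rel_floor floor applied to the relative abundance inside the
#'   dispersion.
#' @return scalar log-probability.
#' @export
reads_loglik <- function(y, x, r, d, rel_floor = 1e-12) {
  stopifnot(length(y) == length(x), r >= 0, any(x > 0))
  rel <- x / sum(x)
  mu <- r * rel
  eps <- d[["d0"]] / pmax(rel, rel_floor) + d[["d1"]]
  sum(nb_logpmf(y, mu, eps))
}

#' Log-likelihood of qPCR replicates given the total latent concentration
#'
#' Each log replicate is Normal with mean `log(sum(x))` and the sample's
#' empirical log-replicate variance.
#'
#' @param Q positive replicate concentrations (cfu/g).
#' @param total total latent abundance `sum(x)` (> 0).
#' @param sigma2 log-scale variance for the sample.
#' @return scalar log-probability.
#' @export
qpcr_loglik <- function(Q, total, sigma2) {
  stopifnot(all(Q > 0), total > 0)
  if (sigma2 <= 0) {
    if (length(unique(Q)) > 1) {
      stop("sigma2 = 0 with distinct replicate values")
    }
    sigma2 <- 1e-12
  }
  sum(stats::dnorm(log(Q), mean = log(total), sd = sqrt(sigma2), log = TRUE))
}

#' Reads-only prior on the total bacterial concentration
#'
#' When a sample has no qPCR measurement the model falls back to a
#' lognormal prior on the total concentration centred at 1e10 cfu/g with
#' log-scale standard deviation 0.1.
#'
#' @param total total latent abundance (> 0).
#' @return log-density.
#' @export
reads_only_prior <- function(total) {
  stopifnot(all(total > 0))
  stats::dnorm(log(total), mean = log(1e10), sd = 0.1, log = TRUE)
}

#' Fit the dispersion constants from technical replicates
#'
#' Maximum-likelihood fit of `(d0, d1)` from a table of technical
#' sequencing replicates, treating each specimen's mean relative abundance
#' (pooled across its replicates) as the true composition and maximizing
#' the negative-binomial likelihood of the observed counts. A
#' method-of-moments regression is available as a cross-check
#' (`method = "moments"`): per (specimen, taxon) the excess-variance
#' statistic `(var - mean)/mean^2` is regressed on `1/rel`.
#'
#' @param replicates data frame with columns `specimen`, `replicate`,
#'   `taxon`, `count`.
#' @param method `"ml"` (default) or `"moments"`.
#' @return list with `d0`, `d1`, `convergence` and `logLik` (ML only).
#' @export
fit_dispersion <- function(replicates, method = c("ml", "moments")) {
  method <- match.arg(method)
  req <- c("specimen", "replicate", "taxon", "count")
  miss <- setdiff(req, names(replicates))
  if (length(miss)) stop("replicate table missing column(s): ",
                         paste(miss, collapse = ", "))
  specs <- unique(replicates$specimen)
  taxa <- unique(replicates$taxon)
  if (length(taxa) < 5) stop("need at least 5 taxa to fit dispersion")

  # per specimen: replicate count matrices (taxa x replicates)
  mats <- lapply(specs, function(sp) {
    sub <- replicates[replicates$specimen == sp, , drop = FALSE]
    reps <- unique(sub$replicate)
    if (length(reps) < 2) {
      stop("specimen ", sp, " has fewer than 2 technical replicates")
    }
    m <- matrix(0, length(taxa), length(reps),
                dimnames = list(taxa, reps))
    m[cbind(match(sub$taxon, taxa), match(sub$replicate, reps))] <- sub$count
    m
  })

  # plug-in truth: mean relative abundance per specimen. The plug-in mean
  # absorbs 1/R of every replicate's variance (R = replicates per
  # specimen), so residuals around it carry only (1 - 1/R) of the model
  # variance; the likelihood models this by deflating the per-observation
  # variance, 1 + eps_eff * mu = (1 - 1/R) * (1 + eps * mu), instead of
  # biasing the fitted constants themselves.
  rels <- lapply(mats, function(m) {
    rel <- rowMeans(sweep(m, 2, colSums(m), "/"))
    pmax(rel, 1e-12)
  })
  Rbar <- mean(vapply(mats, ncol, numeric(1)))
  dof_corr <- Rbar / (Rbar - 1)

  if (method == "moments") {
    stat <- do.call(rbind, lapply(seq_along(mats), function(u) {
      m <- mats[[u]]
      depth <- colSums(m)
      mu <- rels[[u]] %o% depth
      # standardized squared deviation: E[(y-mu)^2 - mu] = eps * mu^2
      ev <- rowMeans((m - mu)^2 - mu) / rowMeans(mu^2)
      data.frame(ev = ev, inv_rel = 1 / rels[[u]])
    }))
    stat <- stat[is.finite(stat$ev), , drop = FALSE]
    fit <- stats::lm(ev ~ inv_rel, data = stat)
    return(list(d0 = max(unname(stats::coef(fit)[2]), 0) * dof_corr,
                d1 = max(unname(stats::coef(fit)[1]), 0) * dof_corr,
                convergence = 0L, logLik = NA_real_))
  }

  nll <- function(par) {
    d0 <- exp(par[1]); d1 <- exp(par[2])
    tot <- 0
    for (u in seq_along(mats)) {
      m <- mats[[u]]
      rel <- rels[[u]]
      eps <- d0 / rel + d1
      shrink <- 1 - 1 / ncol(m)
      for (j in seq_len(ncol(m))) {
        mu <- pmax(rel * sum(m[, j]), 1e-12)
        eps_eff <- pmax((shrink * (1 + eps * mu) - 1) / mu, 1e-12)
        tot <- tot - sum(nb_logpmf(m[, j], mu, eps_eff))
      }
    }
    tot
  }
  opt <- stats::optim(c(log(1e-7), log(0.05)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0) {
    stop("dispersion fit did not converge (code ", opt$convergence,
         "; value ", signif(opt$value, 6), ")")
  }
  list(d0 = exp(opt$par[1]), d1 = exp(opt$par[2]),
       convergence = opt$convergence, logLik = -opt$value)
}
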