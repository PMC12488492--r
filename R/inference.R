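#' Configuration for MCMC inference
#'
#' @param n_burnin burn-in sweeps (proposal scales adapt during burn-in).
#' @param n_samples post-burn-in sweeps kept (before thinning).
#' @param seed RNG seed; every run is bitwise reproducible given the seed.
#' @param module_learning `"on"` learns the module partition under the DP
#'   prior; `"fixed"` freezes it at `fixed_modules` (consensus-module
#'   reruns); `"off"` fixes one taxon per module (the unstructured variant).
#' @param fixed_modules integer partition used when `module_learning =
#'   "fixed"`.
#' @param sparsity_prior `"strong"` (prior inclusion 0.05, for real-data
#'   analyses) or `"noninformative"` (Beta(0.5, 0.5), for recovery
#'   benchmarks) for the interaction indicators.
#' @param reads_only ignore qPCR and use the lognormal prior on total
#'   concentration instead.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param latent_every store full latent trajectories every this many kept
#'   samples (0 = never).
#' @param checkpoint_every write a state checkpoint every this many sweeps
#'   (0 = never); `checkpoint_path` names the RDS file.
#' @param checkpoint_path path for checkpoints.
#' @param proposal_sd initial per-taxon random-walk sd for latent updates
#'   (log scale); adapted during burn-in toward a 0.25-0.6 acceptance rate.
#' @param qpcr_sigma2 optional fixed log-scale qPCR variance overriding the
#'   per-sample empirical variances (used e.g. in simulation studies where
#'   the generating variance is known).
#' @param anneal_factor process-variance inflation applied during the
#'   module-formation stage of burn-in (1 disables tempering).
#' @param rel_floor relative-abundance floor inside the dispersion.
#' @return an `inference_config` list.
#' @export
inference_config <- function(n_burnin = 2500, n_samples = 5000, seed = 1,
                             module_learning = c("on", "fixed", "off"),
                             fixed_modules = NULL,
                             sparsity_prior = c("strong", "noninformative"),
                             reads_only = FALSE, thin = 1, latent_every = 10,
                             checkpoint_every = 0, checkpoint_path = NULL,
                             proposal_sd = 0.2, qpcr_sigma2 = NULL,
                             anneal_factor = 4, rel_floor = 1e-12) {
  module_learning <- match.arg(module_learning)
  sparsity_prior <- match.arg(sparsity_prior)
  stopifnot(n_samples >= 1, n_burnin >= 0, thin >= 1)
  if (module_learning == "fixed" && is.null(fixed_modules)) {
    stop("module_learning = 'fixed' requires fixed_modules")
  }
  structure(list(
    n_burnin = n_burnin, n_samples = n_samples, seed = seed,
    module_learning = module_learning, fixed_modules = fixed_modules,
    sparsity_prior = sparsity_prior, reads_only = reads_only, thin = thin,
    latent_every = latent_every, checkpoint_every = checkpoint_every,
    checkpoint_path = checkpoint_path, proposal_sd = proposal_sd,
    qpcr_sigma2 = qpcr_sigma2, anneal_factor = anneal_factor,
    rel_floor = rel_floor
  ), class = "inference_config")
}

#' Default prior hyperparameters
#'
#' Growth prior centred at a doubling time of 0.7 days with a wide sd;
#' self-interaction prior consistent with carrying capacities around 1e9
#' cfu/g; interaction prior zero-mean on the self-interaction scale;
#' diffuse inverse-Gamma / Gamma priors for the process variance and the
#' DP concentration. Indicator priors are filled in from the sparsity mode
#' at run time.
#'
#' @param m_a1,v_a1 growth prior mean/variance (1/day).
#' @param m_a2,v_a2 self-interaction prior mean/variance.
#' @param v_b interaction prior variance (mean 0).
#' @param v_g perturbation-effect prior variance (mean 0).
#' @param w_shape,w_rate inverse-Gamma prior on the process variance.
#' @param a_shape,a_rate Gamma prior on the DP concentration.
#' @param x0_m,x0_v lognormal prior (log-scale mean/variance) on initial
#'   latent states; diffuse by default.
#' @return a named list of hyperparameters.
#' @export
default_priors <- function(m_a1 = log(2) / 0.7, v_a1 = 25,
                           m_a2 = 1e-9, v_a2 = 1e-16,
                           v_b = 1e-18, v_g = 1,
                           w_shape = 1e-5, w_rate = 1e-5,
                           a_shape = 1e-5, a_rate = 1e-5,
                           x0_m = log(1e7), x0_v = 100) {
  list(m_a1 = m_a1, v_a1 = v_a1, m_a2 = m_a2, v_a2 = v_a2,
       v_b = v_b, v_g = v_g, w_shape = w_shape, w_rate = w_rate,
       a_shape = a_shape, a_rate = a_rate, x0_m = x0_m, x0_v = x0_v)
}

#' Empirical prior construction from a study
#'
#' Sets prior means for growth, self-interaction and interaction magnitude
#' by fitting deterministic logistic growth curves to each taxon on
#' pre-perturbation data (gradient matching: the per-capita log-abundance
#' increment is regressed on abundance, giving intercept = growth and
#' -slope = self-interaction), and sets prior variances by inflating the
#' medians of the empirical estimator variances by 10,000x, keeping the
#' priors diffuse so the data dominate. Taxa whose fit fails fall back to
#' the cohort median with a warning.
#'
#' @param study a filtered `glv_study`.
#' @param inflate variance inflation factor (default 1e4).
#' @return a prior list as in [default_priors()], plus a
#'   `growth_summary` entry reporting the implied mean doubling time.
#' @export
empirical_priors <- function(study, inflate = 1e4) {
  x <- abundance_estimates(study)
  first_pert <- if (!is.null(study$perturbations)) {
    min(study$perturbations$start)
  } else Inf
  n <- nrow(study$taxa)
  a1h <- a2h <- va1 <- va2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pts <- do.call(rbind, lapply(study$subjects, function(s) {
      tt <- study$times[[s]]
      keep <- tt < first_pert
      tt <- tt[keep]
      xi <- x[[s]][i, keep]
      if (length(tt) < 3) return(NULL)
      data.frame(D = diff(log(xi)) / diff(tt), x = xi[-length(xi)])
    }))
    if (is.null(pts) || nrow(pts) < 3) next
    fit <- tryCatch(stats::lm(D ~ x, data = pts), error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) next
    cf <- stats::coef(fit)
    vc <- tryCatch(diag(stats::vcov(fit)), error = function(e) c(NA, NA))
    a1h[i] <- cf[1]; a2h[i] <- -cf[2]
    va1[i] <- vc[1]; va2[i] <- vc[2]
  }
  bad <- !is.finite(a1h)
  if (all(bad)) {
    warning("no taxon admitted a logistic fit; using default priors")
    return(default_priors())
  }
  if (any(bad)) {
    warning(sum(bad), " taxa had degenerate logistic fits; using cohort median")
    a1h[bad] <- stats::median(a1h[!bad])
    a2h[bad] <- stats::median(a2h[!bad])
  }
  m_a1 <- max(mean(pmax(a1h, 0)), 1e-3)
  if (m_a1 <= 1e-3) warning("empirical growth prior mean is approximately 0")
  m_a2 <- max(stats::median(pmax(a2h, 0)), 0)
  v_a1 <- inflate * stats::median(va1, na.rm = TRUE)
  v_a2 <- inflate * stats::median(va2, na.rm = TRUE)
  pr <- default_priors(m_a1 = m_a1, v_a1 = v_a1, m_a2 = m_a2, v_a2 = v_a2,
                       v_b = v_a2)
  pr$growth_summary <- c(mean_growth = m_a1,
                         mean_doubling_days = log(2) / m_a1)
  pr
}

# point estimates of absolute abundance: relative abundance x qPCR total
# (geometric mean over replicates), falling back to 1e10 without qPCR
abundance_estimates <- function(study) {
  rel <- relative_abundances(study)
  out <- list()
  for (s in study$subjects) {
    tot <- vapply(seq_along(study$times[[s]]), function(k) {
      tt <- study$times[[s]][k]
      if (!is.null(study$qpcr)) {
        q <- study$qpcr$value[study$qpcr$subject == s &
                              study$qpcr$time == tt]
        if (length(q)) return(exp(mean(log(q))))
      }
      1e10
    }, numeric(1))
    m <- sweep(rel[[s]], 2, tot, "*")
    m[m <= 0] <- min(m[m > 0], 1e5) * 0.1  # floor numerically absent taxa
    out[[s]] <- m
  }
  out
}

# assemble the per-subject data lists consumed by the C++ kernel
prepare_mcmc_data <- function(study, d, config) {
  pert_names <- if (!is.null(study$perturbations)) {
    unique(study$perturbations$name)
  } else character(0)
  subs <- lapply(study$subjects, function(s) {
    Y <- study$counts[[s]]
    tt <- study$times[[s]]
    K <- length(tt)
    if (K < 2) stop("subject ", s, " has fewer than 2 timepoints")
    H <- pert_activity(study$perturbations, tt, s)
    if (nrow(H) == 0 && length(pert_names) > 0) {
      H <- matrix(0, length(pert_names), K)
    }
    qn <- qmean <- qvar <- rep(0, K)
    emp_vars <- c()
    for (k in seq_len(K)) {
      q <- if (!config$reads_only && !is.null(study$qpcr)) {
        study$qpcr$value[study$qpcr$subject == s & study$qpcr$time == tt[k]]
      } else numeric(0)
      if (length(q) >= 1) {
        qn[k] <- length(q)
        qmean[k] <- mean(log(q))
        qvar[k] <- if (length(q) >= 2) stats::var(log(q)) else NA
        if (length(q) >= 2) emp_vars <- c(emp_vars, qvar[k])
      } else {
        qn[k] <- 1; qmean[k] <- log(1e10); qvar[k] <- 0.01
      }
    }
    if (!is.null(config$qpcr_sigma2)) {
      qvar[qn > 0 & qmean != log(1e10)] <- config$qpcr_sigma2
    }
    fallback <- if (length(emp_vars)) stats::median(emp_vars) else 0.01
    qvar[is.na(qvar) | qvar <= 0] <- max(fallback, 1e-6)
    list(Y = Y, r = colSums(Y), qn = qn, qmean = qmean, qvar = qvar,
         delta = diff(tt), H = H)
  })
  list(subjects = subs, d0 = d[["d0"]], d1 = d[["d1"]],
       relfloor = config$rel_floor, pert_names = pert_names)
}

initial_state <- function(study, config, priors, n_pert) {
  n <- nrow(study$taxa)
  x <- abundance_estimates(study)
  logX <- lapply(study$subjects, function(s) log(x[[s]]))
  c0 <- switch(config$module_learning,
               on = seq_len(n), off = seq_len(n),
               fixed = as.integer(config$fixed_modules))
  M <- max(c0)
  list(logX = logX, a1 = rep(priors$m_a1, n),
       a2 = rep(max(priors$m_a2, 1e-12), n), c = c0,
       b = matrix(0, M, M), zb = matrix(0L, M, M),
       gam = matrix(0, n_pert, M), zg = matrix(0L, n_pert, M),
       sw2 = 1e-3, alpha = 1, prop_sd = rep(config$proposal_sd, n))
}

indicator_priors <- function(config) {
  if (config$sparsity_prior == "strong") {
    list(zb_a = 1, zb_b = 19, zg_a = 0.5, zg_b = 0.5)
  } else {
    list(zb_a = 0.5, zb_b = 0.5, zg_a = 0.5, zg_b = 0.5)
  }
}

#' Prior inclusion probability implied by a config's sparsity mode
#' @param config an `inference_config`.
#' @return named vector with interaction and perturbation prior inclusion
#'   probabilities (used as the prior odds in Bayes factors).
#' @export
prior_inclusion_probability <- function(config) {
  ip <- indicator_priors(config)
  c(interaction = ip$zb_a / (ip$zb_a + ip$zb_b),
    perturbation = ip$zg_a / (ip$zg_a + ip$zg_b))
}

#' Run MCMC inference for the module-structured gLV model
#'
#' Per sweep the Gibbs kernel updates (a) latent trajectories
#' (per-site Metropolis-Hastings in log space against the transition model
#' and the count/qPCR likelihoods), (b) growth, self-interaction,
#' interaction and perturbation coefficients (conjugate Gaussian updates,
#' truncated to enforce positive growth and non-negative self-limitation;
#' coefficients whose indicator is 0 are refreshed from their prior),
#' (c) the spike-and-slab indicators via marginal-likelihood ratios with
#' the coefficient integrated out, (d) module assignments under the DP
#' prior (skipped for `"fixed"`/`"off"`), (e) the process variance
#' (conjugate inverse-Gamma) and (f) the DP concentration (Escobar-West).
#'
#' @param study a filtered `glv_study`.
#' @param d dispersion parameters, list with `d0`, `d1` (see
#'   [fit_dispersion()]).
#' @param config an [inference_config()].
#' @param priors prior list ([default_priors()] or [empirical_priors()]);
#'   defaults to [empirical_priors()] on the study.
#' @return a `glv_posterior` store: iteration-ordered arrays of all model
#'   parameters at taxon level, module assignments, thinned latent
#'   trajectories, chain metadata (seed, config) and latent-update
#'   acceptance rates.
#' @export
run_mcmc <- function(study, d, config = inference_config(), priors = NULL) {
  if (is.null(priors)) priors <- empirical_priors(study)
  priors <- c(priors, indicator_priors(config))
  dat <- prepare_mcmc_data(study, d, config)
  n_pert <- length(dat$pert_names)
  state <- initial_state(study, config, priors, n_pert)

  learn <- config$module_learning == "on"
  ctl <- list(do_latents = TRUE, do_coeffs = TRUE, do_ind_b = TRUE,
              do_ind_g = TRUE, do_modules = learn, do_sw2 = TRUE,
              do_alpha = learn)

  # Burn-in introduces the model components in order of the information
  # they carry, which avoids two well-known traps of a cold start:
  # (1) latent trajectories, growth/self-interaction, perturbation
  # indicators and the process variance settle first; (2) module
  # assignments then form, driven by shared perturbation responses and
  # dynamics; (3) interaction indicators switch on last, at module level.
  # Enabling interaction indicators while every taxon is still its own
  # module would let spurious within-module taxon-pair edges absorb the
  # correlations that module merges need to explain, freezing the
  # partition. Proposal scales adapt during burn-in only.
  set.seed(config$seed)
  if (config$n_burnin > 0) {
    phase <- function(state, n, ...) {
      if (n <= 0) return(state)
      ov <- list(...)
      ctl_p <- utils::modifyList(ctl, ov)
      res <- cpp_run_gibbs(state, dat, priors,
                           c(ctl_p, list(n_sweeps = n, adapt = TRUE,
                                         record_start = 0L, record_thin = 1L,
                                         latent_every = 0L)))
      res$state
    }
    if (learn) {
      n1 <- floor(config$n_burnin / 3)
      n2 <- floor(config$n_burnin / 3)
      n3 <- config$n_burnin - n1 - n2
      state <- phase(state, n1, do_ind_b = FALSE, do_modules = FALSE,
                     do_alpha = FALSE)
      # module-formation phase runs against a tempered process variance:
      # inflating sigma_w^2 lowers the likelihood cost of a correct merge
      # linearly while shrinking its Occam gain only logarithmically, so
      # equivalent taxa coalesce instead of freezing into refinements
      sw2_settled <- state$sw2
      state$sw2 <- state$sw2 * config$anneal_factor
      state <- phase(state, n2, do_ind_b = FALSE, do_sw2 = FALSE)
      state$sw2 <- sw2_settled
      state <- phase(state, n3)
    } else {
      n1 <- floor(config$n_burnin / 2)
      state <- phase(state, n1, do_ind_b = FALSE)
      state <- phase(state, config$n_burnin - n1)
    }
  }
  res <- cpp_run_gibbs(state, dat, priors,
                       c(ctl, list(n_sweeps = config$n_samples,
                                   adapt = FALSE, record_start = 1L,
                                   record_thin = config$thin,
                                   latent_every = config$latent_every)))
  build_posterior(res, study, dat, config, priors)
}

build_posterior <- function(res, study, dat, config, priors) {
  sm <- res$samples
  n <- nrow(study$taxa)
  P <- length(dat$pert_names)
  G <- length(sm$sw2)
  structure(list(
    growth = t(sm$a1), self_interaction = t(sm$a2),
    modules = t(sm$c), n_modules = as.integer(sm$n_modules),
    process_var = as.numeric(sm$sw2), concentration = as.numeric(sm$alpha),
    interactions = array(sm$b_taxon, c(n, n, G)),
    interaction_indicators = array(sm$zb_taxon, c(n, n, G)),
    pert_effects = if (P > 0) array(sm$g_taxon, c(n, P, G)) else NULL,
    pert_indicators = if (P > 0) array(sm$zg_taxon, c(n, P, G)) else NULL,
    latents = sm$latents,
    taxa = study$taxa$id, subjects = study$subjects,
    times = study$times, pert_names = dat$pert_names,
    perturbations = study$perturbations,
    acceptance = as.numeric(res$acceptance),
    config = config, priors = priors, seed = config$seed, n_samples = G
  ), class = "glv_posterior")
}

#' @export
print.glv_posterior <- function(x, ...) {
  cat("glv_posterior:", x$n_samples, "samples,", length(x$taxa), "taxa\n")
  cat("  module count: median", stats::median(x$n_modules),
      " range", min(x$n_modules), "-", max(x$n_modules), "\n")
  cat("  process variance median:", signif(stats::median(x$process_var), 4),
      "\n")
  invisible(x)
}

#' Save / load a posterior store
#'
#' Stores round-trip bit-exactly through RDS serialization.
#' @param store a `glv_posterior`.
#' @param path file path.
#' @return `write_posterior` returns the path invisibly; `read_posterior`
#'   returns the store.
#' @export
write_posterior <- function(store, path) {
  saveRDS(store, path)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) readRDS(path)

#' Split-R-hat convergence diagnostic
#'
#' Splits each chain in half and computes the potential scale reduction
#' factor over the resulting half-chains. Values at or above 1.05 flag
#' insufficient mixing.
#'
#' @param x matrix of draws (iterations x chains), or a list of numeric
#'   vectors of equal length.
#' @return scalar R-hat.
#' @export
split_rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("chains must have at least 4 iterations")
  half <- floor(nrow(x) / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  B <- nn * stats::var(mu)
  W <- mean(apply(sp, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' R-hat table across posterior stores
#'
#' @param stores list of >= 2 `glv_posterior` chains of equal length.
#' @param variables which scalar variable families to include.
#' @param flag_at threshold for the `flagged` column (default 1.05).
#' @return data frame with variable names, R-hat and a flag column.
#' @export
rhat <- function(stores,
                 variables = c("growth", "process_var", "concentration"),
                 flag_at = 1.05) {
  stopifnot(length(stores) >= 2)
  G <- unique(vapply(stores, function(s) s$n_samples, numeric(1)))
  if (length(G) != 1) stop("chains must have equal length")
  rows <- list()
  for (v in variables) {
    if (v %in% c("process_var", "concentration")) {
      r <- split_rhat(vapply(stores, function(s) s[[v]], numeric(G)))
      rows[[length(rows) + 1]] <- data.frame(variable = v, rhat = r)
    } else {
      n <- ncol(stores[[1]][[v]])
      for (i in seq_len(n)) {
        r <- split_rhat(vapply(stores, function(s) s[[v]][, i], numeric(G)))
        rows[[length(rows) + 1]] <- data.frame(
          variable = paste0(v, "[", stores[[1]]$taxa[i], "]"), rhat = r)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$flagged <- out$rhat >= flag_at
  out
}
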