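#' Hold-out forecast from a posterior store
#'
#' Each posterior sample is forward-simulated deterministically (no process
#' variance) from the held-out subject's initial state, with the detection
#' floor applied after every step, and the pointwise median across samples
#' is the forecast.
#'
#' @param store a `glv_posterior` trained without the held-out subject.
#' @param x0 initial abundances of the held-out subject (cfu/g) at
#'   `t_grid[1]`.
#' @param t_grid increasing times (days) at which to forecast.
#' @param perturbations perturbation table for the held-out subject (or
#'   NULL).
#' @param floor clamp for simulated abundances (1e5 cfu/g for absolute
#'   scale; use 1e-6 for relative-abundance forecasts).
#' @param dt simulation step (days).
#' @param max_samples thin the posterior to at most this many samples.
#' @param subject subject id for subject-specific perturbation windows.
#' @return list with `times`, `median` (n x K forecast matrix), and the
#'   number of samples used.
#' @export
holdout_forecast <- function(store, x0, t_grid, perturbations = NULL,
                             floor = 1e5, dt = 0.01, max_samples = 1000,
                             subject = NULL) {
  G <- store$n_samples
  if (G == 0) stop("empty posterior store")
  use <- if (G > max_samples) {
    unique(round(seq(1, G, length.out = max_samples)))
  } else seq_len(G)
  n <- length(store$taxa)
  P <- length(store$pert_names)
  acc <- array(NA_real_, c(n, length(t_grid), length(use)))
  for (u in seq_along(use)) {
    g <- use[u]
    a1 <- store$growth[g, ]
    A <- posterior_interaction_matrix(store, g)
    GT <- if (P > 0) t(store$pert_effects[, , g] *
                       store$pert_indicators[, , g]) else matrix(0, 1, n)
    sim <- simulate_taxon_level(a1, A, GT, x0, t_grid,
                                perturbations = perturbations, sigma_w2 = 0,
                                floor = floor, dt = dt, subject = subject)
    acc[, , u] <- sim$x
  }
  med <- apply(acc, c(1, 2), stats::median)
  list(times = t_grid, median = med, n_samples_used = length(use))
}

#' Root-mean-squared logarithmic error
#'
#' `sqrt(mean((log10 truth - log10 pred)^2))` over timepoints. Both series
#' should already be floored at the detection limit; the error is invariant
#' to a common rescaling of both series.
#'
#' @param truth,pred positive abundance series of equal length.
#' @return RMSLE (log10 units).
#' @export
rmsle <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  stopifnot(all(truth > 0), all(pred > 0))
  sqrt(mean((log10(truth) - log10(pred))^2))
}

#' Hold-one-subject-out forecast errors for a study
#'
#' Convenience wrapper: forecasts the held-out subject from its first
#' retained timepoint and scores per-taxon RMSLE against the subject's
#' measured abundances (relative abundance times qPCR total). Taxa with
#' zero reads at a timepoint are excluded from that timepoint's score;
#' both measurements and forecasts are clamped at `floor` before scoring.
#'
#' @param store posterior trained on the remaining subjects.
#' @param study the full study (supplies held-out measurements).
#' @param subject held-out subject id.
#' @param floor detection floor (cfu/g).
#' @param dt simulation step.
#' @param max_samples posterior thinning cap.
#' @return data frame with taxon, subject and rmsle.
#' @export
holdout_errors <- function(store, study, subject, floor = 1e5, dt = 0.01,
                           max_samples = 1000) {
  x <- abundance_estimates(study)[[subject]]
  tt <- study$times[[subject]]
  x0 <- pmax(x[, 1], floor)
  fc <- holdout_forecast(store, x0, tt, study$perturbations,
                         floor = floor, dt = dt, max_samples = max_samples,
                         subject = subject)
  cnt <- study$counts[[subject]]
  out <- lapply(seq_len(nrow(cnt)), function(i) {
    keep <- cnt[i, ] > 0
    if (!any(keep)) return(NULL)
    data.frame(taxon = study$taxa$id[i], subject = subject,
               rmsle = rmsle(pmax(x[i, keep], floor),
                             pmax(fc$median[i, keep], floor)))
  })
  do.call(rbind, out)
}

#' Paired comparison of forecast errors between two methods
#'
#' Wilcoxon signed-rank test on per-(taxon, subject) RMSLE pairs; ties
#' (zero differences) are dropped per the standard convention. With fewer
#' than 6 pairs a warning is emitted and the exact null distribution is
#' used.
#'
#' @param errors_a,errors_b data frames with columns `taxon`, `subject`,
#'   `rmsle` (as from [holdout_errors()]).
#' @param alternative `"less"` tests whether method A's errors are smaller.
#' @return list with `statistic`, `p`, `n_pairs`.
#' @export
compare_methods <- function(errors_a, errors_b,
                            alternative = c("less", "greater",
                                            "two.sided")) {
  alternative <- match.arg(alternative)
  key_a <- paste(errors_a$taxon, errors_a$subject)
  key_b <- paste(errors_b$taxon, errors_b$subject)
  common <- intersect(key_a, key_b)
  a <- errors_a$rmsle[match(common, key_a)]
  b <- errors_b$rmsle[match(common, key_b)]
  keep <- a != b  # drop ties
  n <- sum(keep)
  if (n < 6) {
    warning("fewer than 6 informative pairs; using the exact distribution")
  }
  if (n == 0) {
    return(list(statistic = NA_real_, p = 1, n_pairs = 0))
  }
  wt <- stats::wilcox.test(a[keep], b[keep], paired = TRUE,
                           alternative = alternative, exact = n < 50)
  list(statistic = unname(wt$statistic), p = wt$p.value, n_pairs = n)
}

#' Benjamini-Hochberg correction across method comparisons
#'
#' @param comparisons data frame with a `p` column (one row per
#'   comparison).
#' @return the data frame with a `q` column appended.
#' @export
adjust_comparisons <- function(comparisons) {
  comparisons$q <- stats::p.adjust(comparisons$p, method = "BH")
  comparisons
}
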