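#' Perturbation activity matrix
#'
#' Evaluates the step functions h_p(t) for each perturbation at the given
#' times. A perturbation is active on the half-open interval [start, end).
#' Perturbations are ordered by first appearance of their name, and this
#' ordering defines the row index p used throughout the package (matching
#' rows of `pert_effects`).
#'
#' @param perturbations data frame with columns `name`, `start`, `end` and
#'   optionally `subject`, or NULL for none.
#' @param times numeric vector of times (days).
#' @param subject if given and the table has a `subject` column, only rows
#'   for that subject are used.
#' @return P x length(times) binary matrix (P = number of distinct names).
#' @export
pert_activity <- function(perturbations, times, subject = NULL) {
  if (is.null(perturbations) || nrow(perturbations) == 0) {
    return(matrix(0, 0, length(times)))
  }
  nms <- unique(perturbations$name)
  H <- matrix(0, length(nms), length(times))
  rownames(H) <- nms
  tab <- perturbations
  if (!is.null(subject) && "subject" %in% names(tab)) {
    tab <- tab[tab$subject == subject, , drop = FALSE]
  }
  for (r in seq_len(nrow(tab))) {
    p <- match(tab$name[r], nms)
    H[p, ] <- H[p, ] | (times >= tab$start[r] & times < tab$end[r])
  }
  H * 1
}

#' Deterministic drift of the stochastic gLV dynamics
#'
#' Component i of the drift is
#' `x_i * [ (1 + sum_p gamma[p, c_i] z_gamma[p, c_i] h_p(t)) * a1_i
#'          - a2_i * x_i + sum_{j: c_j != c_i} b[c_i, c_j] z_b x_j ]`
#' i.e. perturbations modulate growth multiplicatively, self-limitation is
#' quadratic, and interactions act between modules only.
#'
#' @param x state vector (cfu/g), >= 0.
#' @param params a `glv_params` object.
#' @param t time in days (used to evaluate perturbation windows).
#' @param perturbations perturbation table (see [pert_activity()]), or NULL.
#' @param subject optional subject id for subject-specific windows.
#' @return drift vector dx/dt (cfu/g per day).
#' @export
glv_drift <- function(x, params, t = 0, perturbations = NULL, subject = NULL) {
  if (any(x < 0)) stop("negative abundances are not allowed")
  h <- pert_activity(perturbations, t, subject)[, 1]
  A <- expand_to_taxa(params)
  G <- expand_pert_to_taxa(params)
  gmod <- if (length(h)) 1 + as.numeric(crossprod(G, h)) else rep(1, length(x))
  x * (params$growth * gmod + as.numeric(A %*% x))
}

#' One-step log-scale mean of the discretized dynamics
#'
#' First-order discretization of the stochastic gLV model: the next latent
#' log-abundance is Normal with mean
#' `log mu(k+1) = log x(k) + delta * [bracket]` and variance
#' `delta * sigma_w^2`, where the bracket is the per-capita growth of
#' [glv_drift()] evaluated at x(k).
#'
#' @param x current state vector (> 0).
#' @param params a `glv_params` object.
#' @param delta timestep in days (> 0).
#' @param pert_on binary vector of active perturbations (length P).
#' @return vector `log mu(k+1)`.
#' @export
step_mean_log <- function(x, params, delta,
                          pert_on = rep(0, n_perturbations(params))) {
  if (delta <= 0) stop("delta must be positive")
  if (any(x <= 0)) stop("states must be strictly positive")
  A <- expand_to_taxa(params)
  G <- expand_pert_to_taxa(params)
  gmod <- if (length(pert_on)) 1 + as.numeric(crossprod(G, pert_on)) else 1
  log(x) + delta * (params$growth * gmod + as.numeric(A %*% x))
}

#' Forward-simulate gLV trajectories
#'
#' Iterates the first-order log-space discretization on an internal fine grid
#' (`dt`, default 0.01 day) and reads values off at the requested output
#' times (nearest grid point). In `"stochastic"` mode Gaussian log-scale
#' noise with variance `dt * process_var` is added each step; in
#' `"deterministic"` mode the simulation is seed-independent. After every
#' step states are clamped below at `floor` and capped above at `cap`;
#' trajectories hitting the cap are flagged divergent rather than erroring,
#' since explosive posterior samples are expected and medians over samples
#' remain usable.
#'
#' @param params a `glv_params` object.
#' @param x0 initial state (> 0), at time `t_grid[1]`.
#' @param t_grid increasing vector of output times (days).
#' @param perturbations perturbation table or NULL.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param floor lower clamp (cfu/g), default 1e5 (limit of detection).
#' @param dt internal simulation step (days).
#' @param cap upper cap (cfu/g) for divergence flagging.
#' @param subject optional subject id for perturbation windows.
#' @return list with `times`, `x` (n x length(t_grid) matrix) and
#'   `divergent` (logical, any state hit the cap).
#' @export
forward_simulate <- function(params, x0, t_grid, perturbations = NULL,
                             mode = c("deterministic", "stochastic"),
                             floor = 1e5, dt = 0.01, cap = 1e15,
                             subject = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(x0 > 0), all(diff(t_grid) > 0))
  A <- expand_to_taxa(params)
  G <- expand_pert_to_taxa(params)
  simulate_taxon_level(params$growth, A, G, x0, t_grid,
    perturbations = perturbations,
    sigma_w2 = if (mode == "stochastic") params$process_var else 0,
    floor = floor, dt = dt, cap = cap, subject = subject
  )
}

#' Forward simulation from taxon-level parameters
#'
#' Workhorse behind [forward_simulate()], [holdout_forecast()] and
#' [keystoneness()]: simulates from an explicit taxon-level interaction
#' matrix `A` (diagonal = negative self-interactions) and taxon-level
#' perturbation effect matrix, so posterior samples can be simulated without
#' rebuilding `glv_params` objects.
#'
#' @inheritParams forward_simulate
#' @param growth per-taxon growth rates.
#' @param A taxon-level interaction matrix.
#' @param pert_taxa P x n matrix of effective perturbation effects.
#' @param sigma_w2 process variance (0 for deterministic).
#' @return same structure as [forward_simulate()].
#' @export
simulate_taxon_level <- function(growth, A, pert_taxa, x0, t_grid,
                                 perturbations = NULL, sigma_w2 = 0,
                                 floor = 1e5, dt = 0.01, cap = 1e15,
                                 subject = NULL) {
  n <- length(growth)
  t0 <- t_grid[1]
  t_end <- t_grid[length(t_grid)]
  nsteps <- max(0L, as.integer(ceiling((t_end - t0) / dt - 1e-9)))
  step_times <- t0 + dt * (0:nsteps)
  H <- pert_activity(perturbations, step_times, subject)
  # align design perturbations with the parameter set: a design window the
  # parameters carry no effect for contributes zero, and vice versa
  P <- max(nrow(H), nrow(pert_taxa), 1L)
  if (nrow(H) < P) H <- rbind(H, matrix(0, P - nrow(H), ncol(H)))
  if (nrow(pert_taxa) < P) {
    pert_taxa <- rbind(pert_taxa, matrix(0, P - nrow(pert_taxa), n))
  }
  out_idx <- vapply(t_grid, function(tt) which.min(abs(step_times - tt)),
                    integer(1))
  res <- cpp_glv_simulate(log(pmax(x0, floor)), growth, A, pert_taxa, H,
                          dt, sigma_w2, log(floor), log(cap),
                          out_idx - 1L)
  list(times = t_grid, x = res$x, divergent = res$divergent)
}
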