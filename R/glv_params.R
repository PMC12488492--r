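#' Parameter set for a module-structured generalized Lotka-Volterra system
#'
#' Bundles all dynamical parameters of the module-structured gLV model:
#' per-taxon growth rates and self-interactions, the assignment of taxa to
#' interaction modules, module-module interaction strengths with binary
#' inclusion indicators, perturbation effects with their own indicators, the
#' process variance of the multiplicative (geometric Brownian motion)
#' stochastic component, and the Dirichlet-process concentration.
#'
#' Taxa in the same module share incoming/outgoing interactions and
#' perturbation responses; intramodule interactions are structurally zero.
#'
#' @param growth numeric vector, per-taxon growth rates (1/day), all > 0.
#' @param self_interaction numeric vector, per-taxon self-limitation
#'   coefficients (1/(cfu/g * day)), all >= 0.
#' @param modules integer vector, module index of each taxon (contiguous
#'   1..M).
#' @param interactions M x M numeric matrix of module-module interaction
#'   strengths (effect of column module on row module, 1/(cfu/g * day)).
#'   Diagonal entries are ignored (no intramodule interactions).
#' @param interaction_indicators M x M binary matrix; an interaction only
#'   enters the dynamics when its indicator is 1.
#' @param pert_effects P x M numeric matrix of perturbation effects on module
#'   growth rates (dimensionless multipliers; growth is scaled by
#'   1 + sum of active effects).
#' @param pert_indicators P x M binary matrix of perturbation inclusion
#'   indicators.
#' @param process_var variance rate of log-abundance noise (1/day), >= 0.
#' @param concentration Dirichlet-process concentration parameter, > 0.
#' @return An object of class `glv_params`.
#' @export
glv_params <- function(growth,
                       self_interaction,
                       modules = seq_along(growth),
                       interactions = NULL,
                       interaction_indicators = NULL,
                       pert_effects = NULL,
                       pert_indicators = NULL,
                       process_var = 0,
                       concentration = 1) {
  n <- length(growth)
  modules <- as.integer(modules)
  M <- max(modules)
  if (is.null(interactions)) interactions <- matrix(0, M, M)
  if (is.null(interaction_indicators)) {
    interaction_indicators <- matrix(as.numeric(interactions != 0), M, M)
  }
  if (is.null(pert_effects)) pert_effects <- matrix(0, 0, M)
  if (is.null(pert_indicators)) {
    pert_indicators <- matrix(1, nrow(pert_effects), M)
  }
  obj <- structure(list(
    growth = as.numeric(growth),
    self_interaction = as.numeric(self_interaction),
    modules = modules,
    interactions = interactions,
    interaction_indicators = interaction_indicators,
    pert_effects = pert_effects,
    pert_indicators = pert_indicators,
    process_var = process_var,
    concentration = concentration
  ), class = "glv_params")
  validate_glv_params(obj)
  obj
}

#' @rdname glv_params
#' @param x object to validate.
#' @export
validate_glv_params <- function(x) {
  n <- length(x$growth)
  M <- max(x$modules)
  stopifnot(
    length(x$self_interaction) == n,
    length(x$modules) == n,
    all(x$growth > 0),
    all(x$self_interaction >= 0),
    all(sort(unique(x$modules)) == seq_len(M)),
    nrow(x$interactions) == M, ncol(x$interactions) == M,
    all(dim(x$interaction_indicators) == c(M, M)),
    ncol(x$pert_effects) == M || nrow(x$pert_effects) == 0,
    all(dim(x$pert_indicators) == dim(x$pert_effects)),
    x$process_var >= 0,
    x$concentration > 0
  )
  invisible(x)
}

#' Number of taxa / modules / perturbations in a parameter set
#' @param params a `glv_params` object.
#' @return integer count.
#' @export
n_taxa <- function(params) length(params$growth)

#' @rdname n_taxa
#' @export
n_modules <- function(params) max(params$modules)

#' @rdname n_taxa
#' @export
n_perturbations <- function(params) nrow(params$pert_effects)

#' Expand module-level interactions to a taxon-level interaction matrix
#'
#' Builds the n x n matrix `A` used by stability and forecasting analyses:
#' `A[i, j] = b[c_i, c_j] * z[c_i, c_j]` for taxa in different modules,
#' `A[i, j] = 0` for distinct taxa sharing a module, and
#' `A[i, i] = -self_interaction[i]` on the diagonal.
#'
#' @param params a `glv_params` object.
#' @return n x n numeric matrix.
#' @export
expand_to_taxa <- function(params) {
  validate_glv_params(params)
  c_i <- params$modules
  eff <- params$interactions * params$interaction_indicators
  A <- eff[c_i, c_i, drop = FALSE]
  same <- outer(c_i, c_i, `==`)
  A[same] <- 0
  diag(A) <- -params$self_interaction
  dimnames(A) <- NULL
  A
}

#' Effective taxon-level perturbation effects
#'
#' @param params a `glv_params` object.
#' @return P x n matrix of indicator-gated perturbation effects per taxon.
#' @export
expand_pert_to_taxa <- function(params) {
  eff <- params$pert_effects * params$pert_indicators
  eff[, params$modules, drop = FALSE]
}

#' Count of pairwise interaction parameters among n units
#'
#' The gLV model has one directed interaction per ordered pair of distinct
#' units, i.e. `n * (n - 1)` parameters. Module structure replaces the
#' taxon-level count with the (much smaller) module-level count.
#'
#' @param n_units number of taxa or modules (>= 1).
#' @return integer, `n_units * (n_units - 1)`.
#' @export
count_interaction_parameters <- function(n_units) {
  stopifnot(n_units >= 1)
  as.numeric(n_units) * (as.numeric(n_units) - 1)
}

#' Expected number of modules under the Dirichlet-process prior
#'
#' For `n` taxa and concentration `alpha`, the expected number of occupied
#' modules is approximately `alpha * log((n + alpha) / alpha)`, growing
#' logarithmically in `n`.
#'
#' @param alpha DP concentration parameter (> 0).
#' @param n number of taxa (>= 1).
#' @return expected module count (real).
#' @export
expected_module_count <- function(alpha, n) {
  stopifnot(alpha > 0, n >= 1)
  alpha * log((n + alpha) / alpha)
}
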