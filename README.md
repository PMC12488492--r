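# glvmod

Bayesian inference of **module-structured generalized Lotka–Volterra
(gLV) dynamics** from longitudinal microbiome data — 16S read counts plus
qPCR total-concentration measurements — with uncertainty-quantified
interaction networks and downstream ecosystem analyses.

## Who this is for

Microbiome researchers with dense time-series data from a perturbed
cohort (e.g. gnotobiotic mice through diet/antibiotic windows) who want a
dynamical-systems view of their community: which taxa promote or inhibit
which, how perturbations act, which groups of taxa are keystone, and
whether the inferred ecology is stable.

## The model

Taxon $i$ in subject $s$ follows stochastic gLV dynamics

$$
\mathrm{d}x_{s,i} = x_{s,i}\Big[\big(1+\textstyle\sum_p \gamma_{p,c_i}
z^{(\gamma)}_{p,c_i} h_p(t)\big) a_{1,i} - a_{2,i} x_{s,i}
+ \textstyle\sum_{j: c_j\neq c_i} b_{c_i,c_j} z^{(b)}_{c_i,c_j}
x_{s,j}\Big] + x_{s,i}\,\mathrm{d}w_{s,i},
$$

where taxa are clustered into **interaction modules** $c_i$ under a
Dirichlet-process prior: members of a module share all interactions and
perturbation responses, so the number of interaction parameters grows as
$O(\log^2 N)$ instead of $O(N^2)$ (141 taxa: 19,740 pairwise parameters;
17 modules: 272). Spike-and-slab indicators $z$ on every module-level
edge yield **Bayes factors** for edge evidence (substantial/strong/
decisive at $10^{0.5}$/10/100). Counts are negative-binomial with
abundance-dependent dispersion $\epsilon = d_0/\mathrm{rel} + d_1$; qPCR
replicates are lognormal around the total latent concentration. All
parameters — latent trajectories included — are sampled by a Gibbs/
Metropolis MCMC with collapsed (coefficient-marginalized) module moves,
implemented in C++.

Downstream: consensus modules and fixed-cluster reruns, signed module
networks (GraphML export), hold-one-subject-out forecasting with RMSLE
scoring, module keystoneness, eigenvalue stability with an
in-degree-preserving permutation null, signed cycle censuses and the
mutualism-to-competition ratio, and hypergeometric taxonomic enrichment.
Synthetic and semi-synthetic cohort generators with recovery metrics
(AUC-ROC, Spearman) support benchmarking.

## Worked example

Read a study from the five-table format (taxa, counts, sample metadata,
qPCR, perturbations), or simulate one; infer; summarize:

```r
library(glvmod)

dir <- system.file("extdata", "toy_study", package = "glvmod")
study <- read_study(file.path(dir, "taxa.tsv"), file.path(dir, "counts.tsv"),
                    file.path(dir, "metadata.tsv"), file.path(dir, "qpcr.tsv"),
                    file.path(dir, "perturbations.tsv"))
study
#> glv_study: 3 taxa, 2 subjects, 8 samples
#>   timepoints per subject: 4, 4
#>   perturbations: highfat
#>   qPCR samples: 8

# a synthetic 8-taxon cohort with known modules and one perturbation
truth <- make_ground_truth(n_taxa = 8, n_modules = 3, density = 0.5,
                           seed = 11, n_perturbations = 1, pert_density = 1,
                           min_edges = 2)
x0 <- sample_initial_conditions(3, meanlog = rep(log(1e7), 8),
                                sdlog = rep(0.8, 8), seed = 12)
pert <- data.frame(name = "antibiotic", start = 10, end = 17)
cohort <- simulate_cohort(truth, times = 0:27, x0 = x0, perturbations = pert,
                          trajectories = "stochastic", dt = 1, seed = 13)

fit <- run_mcmc(cohort, d = list(d0 = 4.2e-8, d1 = 6.05e-2),
                inference_config(n_burnin = 1000, n_samples = 1000, seed = 1,
                                 sparsity_prior = "noninformative"))
fit
#> glv_posterior: 1000 samples, 8 taxa
#>   module count: median 3  range 3 - 4
#>   process variance median: 0.01602

m <- recovery_metrics(fit, truth)
#> interaction AUC 0.82 | co-cluster AUC 0.84 | growth Spearman 0.93

consensus_modules(cocluster_matrix(fit), fit)
#> [1] 1 2 3 1 3 2 1 3   (true modules: 3 2 1 2 1 2 3 1)
```

The module count settles at the true value of 3, the chain recovers most
of the partition (co-cluster AUC 0.84 in this one-minute run; longer
chains and the full benchmark design reach 1.0), and the process variance
posterior sits near the generating value 0.01. `extract_network()` on a
fixed-cluster rerun gives the signed, Bayes-factor-annotated module
network; `keystoneness()`, `stability_profile()`, `cycle_census()` and
`holdout_forecast()` take it from there.

A command-line front end wrapping the same functions ships at
`inst/cli/glvmod-cli.R` (subcommands: filter, fit-dispersion, infer,
consensus, forecast, keystoneness, stability, cycles, enrichment,
semisynth, benchmark).

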