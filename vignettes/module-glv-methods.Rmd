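---
title: "Module-structured Lotka-Volterra inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-structured Lotka-Volterra inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`glvmod` infers an interpretable dynamical-systems model of a microbial
community from longitudinal 16S read counts and qPCR total-concentration
measurements. The dynamics are stochastic generalized Lotka-Volterra (gLV):
taxon $i$ in subject $s$ evolves as

$$
\mathrm{d}x_{s,i} = x_{s,i}(t)\Big[\big(1 + \textstyle\sum_p
\gamma_{p,c_i} z^{(\gamma)}_{p,c_i} h_p(t)\big)\,a_{1,i}
- a_{2,i}\,x_{s,i}(t)
+ \textstyle\sum_{j:\,c_j \ne c_i} b_{c_i,c_j} z^{(b)}_{c_i,c_j}
x_{s,j}(t)\Big] + x_{s,i}(t)\,\mathrm{d}w_{s,i},
$$

with growth rates $a_{1,i}$ (1/day), self-limitation $a_{2,i}$
(1/(cfu/g·day)), module assignments $c_i$, module-module interaction
strengths $b$ with binary inclusion indicators $z^{(b)}$, perturbation
effects $\gamma$ (dimensionless growth modulation on half-open windows
$h_p(t)$) with indicators $z^{(\gamma)}$, and multiplicative (geometric
Brownian) process noise with variance rate $\sigma_w^2$. Taxa in the same
module share all incoming/outgoing interactions and perturbation
responses; intramodule interactions are structurally zero. The module
partition carries a Dirichlet-process prior with concentration $\alpha$,
under which the expected module count is
$\alpha \log\{(N+\alpha)/\alpha\}$ — interaction complexity grows as
$O(\log^2 N)$ rather than $O(N^2)$, which is the point of the module
structure (141 taxa: 19,740 ordered-pair parameters; 17 modules: 272).

For inference the dynamics are discretized to first order in log space at
the observation timepoints:
$\log x(k{+}1) \sim \mathrm{Normal}(\log\mu(k{+}1),\,\Delta_k\sigma_w^2)$
with $\log\mu(k{+}1) = \log x(k) + \Delta_k\,[\text{bracket above}]$.
The fixed points of this map coincide with the continuous equilibria, so
steady-state analyses are step-size independent.

Measurements are modelled per modality. Counts are negative-binomial with
mean $\varphi = r\,x_i/\sum_j x_j$ (read depth $r$ is conditioned on) and
dispersion $\epsilon = d_0/\mathrm{rel} + d_1$ in the excess-variance
parameterization (variance $= \varphi + \epsilon\varphi^2$); low-abundance
taxa are the most overdispersed, which is the behaviour the
$d_0/\mathrm{rel}$ term encodes. qPCR replicates are lognormal around the
total latent concentration with the per-sample empirical variance of log
replicates (natural logs internally; single-replicate samples fall back
to the median empirical variance). Samples without qPCR use a lognormal
prior on the total, centred at $10^{10}$ cfu/g with log-sd 0.1.

## Priors and tunable parameters

* Growth prior: truncated normal, $a_1 > 0$; default mean $\ln 2 / 0.7$
  (a 0.7-day doubling time). `empirical_priors()` instead fits
  deterministic logistic curves per taxon on pre-perturbation data by
  gradient matching (per-capita log-increments regressed on abundance)
  and inflates the median empirical estimator variances by $10^4$, so
  priors stay diffuse and data-dominated.
* Self-interaction: truncated normal, $a_2 \ge 0$, consistent with
  carrying capacities around $10^9$ cfu/g.
* Interactions and perturbation effects: zero-mean Gaussian slabs
  (variances `v_b`, `v_g`) under spike-and-slab indicators with a
  collapsed Beta-Bernoulli prior. `"strong"` sparsity (real-data
  analyses) uses Beta(1, 19), prior inclusion 0.05; `"noninformative"`
  (recovery benchmarks) uses Beta(0.5, 0.5). The prior inclusion
  probability is exactly what Bayes factors divide by.
* Process variance: diffuse inverse-Gamma(1e-5, 1e-5); DP concentration:
  diffuse Gamma(1e-5, 1e-5) with the Escobar-West auxiliary update.
* Initial latent states: lognormal prior, by default log-mean
  $\log 10^7$ with log-variance 100. The transition model alone leaves
  $x(0)$ improper; a proper (if very diffuse) anchor is required for a
  well-defined joint model and for joint-distribution testing.

## MCMC design

Each Gibbs sweep updates, in order: latent log-trajectories (per-site
Metropolis-Hastings against the two adjacent transitions, the count and
qPCR likelihoods, and all cross-taxon terms the site enters);
growth/self-interaction/interaction/perturbation coefficients (conjugate
Gaussian, truncated where positivity applies; indicator-off coefficients
are refreshed from the prior); indicators (Bernoulli full conditionals
with the coefficient integrated out analytically); module assignments;
process variance (conjugate inverse-Gamma); and the concentration.

Module moves are the delicate part. A single-taxon move is evaluated with
the interaction and perturbation coefficients **marginalized in closed
form**: conditional on the indicators the coefficients enter the
transition means linearly, the evidence factorizes over target modules,
and each block needs only a small Gaussian integral (regressors are
rescaled to unit prior variance, which keeps the linear algebra well
conditioned despite abundance-sum regressors of order $10^9$).
A candidate new module draws its indicators from the conditional
(Polya-urn) prior, in the style of auxiliary-variable DP samplers.
Because other phases condition on coefficient values, the coefficients
are redrawn from their full conditional immediately after the module
sweep (a partially collapsed Gibbs scheme; skipping this redraw would
target the wrong joint distribution).

Cold starts need care: enabling everything at once traps the partition.
Burn-in therefore introduces components in information order —
(1) latents, coefficients, perturbation indicators and the process
variance; (2) module moves, run against a process variance tempered by
`anneal_factor` (default 4: inflating $\sigma_w^2$ lowers the likelihood
cost of a correct merge linearly while shrinking its Occam gain only
logarithmically, so equivalent taxa coalesce instead of freezing into
refinements); (3) interaction indicators, at module level. Turning
interaction indicators on while every taxon is still a singleton lets
spurious within-module taxon-pair edges absorb exactly the correlations
that module merges need to explain, and the partition freezes — that
failure mode motivated the schedule. Latent proposal scales adapt during
burn-in only; the recorded chain is a fixed-kernel Markov chain, and runs
are bitwise reproducible given the seed.

Correctness of the full kernel is validated by a joint-distribution
("getting it right") test: alternating kernel transitions with data
redraws must leave every parameter's marginal equal to its prior. The
test suite runs this on a 3-taxon model and compares growth,
self-interaction, process variance, module count and concentration
against direct prior draws (Kolmogorov-Smirnov / chi-squared, threshold
p > 0.01). The harness uses moderately informative proper priors; very
heavy-tailed process-variance priors occasionally draw explosive systems
whose latents exceed the sampler's proposal guard, which would bias the
comparison for reasons unrelated to kernel correctness.

## Downstream analyses

* **Bayes factors.** For each edge,
  $\mathrm{BF} = \{p/(1-p)\}\,/\,\{p_0/(1-p_0)\}$ from posterior
  inclusion frequency $p$ and prior inclusion $p_0$; tiers at
  $10^{0.5}$ ("substantial"), $10$ ("strong"), $100$ ("decisive").
  Monte-Carlo-degenerate frequencies 0/1 are shifted by $1/(2G)$ so the
  BF stays finite (flagged). Network extraction requires a fixed-cluster
  posterior; conditional-median strengths whose central 95% interval
  straddles zero are flagged rather than silently signed.
* **Consensus modules.** Average-linkage agglomerative clustering on
  $1 - $ co-clustering probability, cut at the median posterior module
  count (rounded half-up). Linkage is exposed; average linkage is the
  default choice.
* **Keystoneness.** Per posterior sample, the full community and the
  community with module $m$ removed are simulated deterministically for
  100 days from the same initial state (by default the posterior latent
  state at the last pre-perturbation observed timepoint); final states
  average the last 12 h; $k(m)$ is minus the mean outside-module change
  of $\log_{10}(x + 10^5)$. Simulation uses the detection floor
  $10^5$ cfu/g; because log-Euler fixed points equal the continuous
  equilibria, the toy two-taxon system reproduces its analytic value
  $\log_{10} 2$ to three decimals.
* **Stability.** Counts of right-half-plane eigenvalues of the
  taxon-level interaction matrix per posterior sample (perturbation terms
  excluded: they are off at steady state), compared against
  in-degree-preserving permutations — performed at module level when the
  partition is fixed, then expanded.
* **Cycles.** Simple directed 2-/3-cycles classified by edge-sign
  multiset, rotation-invariant, both triangle orientations counted;
  mutualism-to-competition ratio (MCR) with $x/0 = \infty$ and $0/0$
  undefined. Permutation p-values use the add-one convention.
* **Forecasting.** Hold-one-subject-out: every posterior sample is
  simulated deterministically (no process noise) from the held-out
  subject's first retained state, clamped at $10^5$ cfu/g (absolute) or
  $10^{-6}$ (relative); the pointwise median across samples is the
  forecast, scored by RMSLE in $\log_{10}$; taxa with zero reads at a
  timepoint are excluded from that timepoint's score. Method comparisons
  use paired Wilcoxon signed-rank tests (ties dropped, exact distribution
  under ~50 pairs) with Benjamini-Hochberg correction.

## Synthetic data: what it emulates and what it does not

`make_ground_truth()` draws gLV systems at a healthy gut scale: lognormal
growth around a 0.7-day doubling time, carrying capacities
$10^8$–$10^{10}$ cfu/g, module-level interactions whose per-capita effect
of a full source module is `interaction_scale` times a typical growth
rate (scaled by source-module size so sizes do not change the ecology),
and module-specific perturbation effects. Draws are screened by pilot
simulations — deterministic plus stochastic replicates under the planned
perturbation design — requiring every taxon to exceed the detection floor
and persist; optionally a minimum edge count. `simulate_cohort()` then
simulates trajectories (deterministic by default; optionally with the
model's own process noise) and corrupts them with the model's measurement
distributions: lognormal read depth around 75,000, negative-binomial
counts at the abundance-dependent dispersion, lognormal qPCR replicates.
Realized count totals are recorded as the read depths. The ten-taxon
challenge benchmark instead introduces its tenth taxon at day 10 and
draws reads from a Dirichlet-multinomial.

The desk-scale recovery benchmark (`recovery_benchmark()`) is a 12-taxon,
3-module, 4-subject cohort sampled daily for 64 days with four one-week
perturbation windows, every module responding to every perturbation,
interactions at 0.8 growth-scale with at least two module edges, and
ground-truth trajectories drawn from the model's own discretized
stochastic dynamics. These choices mirror the perturbation-rich design
philosophy of real gnotobiotic experiments: perturbations and process
noise are what decorrelate a taxon's own abundance from the module sums,
and without them module-level interactions are close to unidentifiable
from equilibrium data (they get absorbed into self-limitation). Under
these conditions the package recovers interactions and co-clustering with
median AUC-ROC at or near 1.0 over five seeds (2,000 + 2,000 MCMC
sweeps per run), degrading when timepoints are downsampled to 1/2 and
1/4 — strictly monotonically for interaction AUC; co-clustering degrades
relative to the full series at both fractions but is not ordered between
them, because the downsampler always retains perturbation-window onsets
and those carry most of the module-identity information.

Passing these tests shows the sampler inverts its own generative model at
realistic noise levels and scale — it does not show that real gut
communities follow gLV dynamics, that modules exist in a given dataset,
or that the measurement model captures protocol-specific artefacts (PCR
bias, batch effects are out of scope).

## Numerical choices and degenerate inputs

* Simulation grid: log-Euler with `dt = 0.01` day, values read at nearest
  grid points; clamped below at the detection floor in
  simulation/forecast contexts only (never inside the likelihood), capped
  at $10^{15}$ cfu/g with a divergence flag instead of an error, because
  explosive posterior samples are expected and medians remain usable.
* Relative abundances are floored at $10^{-12}$ inside the dispersion.
* Zero counts are retained as data (no pseudocounts).
* The dispersion fit treats each specimen's mean relative abundance as
  truth and maximizes the count likelihood over $(d_0, d_1)$; the plug-in
  mean absorbs $1/R$ of each replicate's variance, which the likelihood
  models by deflating per-observation variance (rather than by biasing
  the constants); a method-of-moments regression is provided as a
  cross-check. $d_0$ is only identifiable when rare taxa
  (rel $\lesssim 10^{-5}$) are sequenced deeply.
* The abundance filter (0.01% relative abundance at 7 consecutive
  timepoints in 2 subjects by default) is applied to the raw timepoint
  sequence, ignoring perturbation boundaries.
* Downsampling retains `ceiling(fraction * K)` timepoints by uniform
  stride, swapping in the first timepoint and each perturbation-window
  onset; the original scheme is only shown graphically in the literature,
  so this stride rule is a documented stand-in.
* Posterior stores persist via RDS (bit-exact round trips); summaries as
  TSV; networks as GraphML.

## Known limitations

Single-site latent updates and single-taxon module moves mix slowly on
large systems; the intended workflow at cohort scale is the one the
tooling supports — multiple seeds, consensus modules, then a
fixed-cluster rerun for edge-stable summaries. Hold-one-subject-out
forecasting refits the model per fold by design. Comparator inference
methods (penalized-regression gLV variants, compositional models) are
deliberately not reimplemented; their predictions can be imported as TSV
and scored with the same RMSLE machinery.
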