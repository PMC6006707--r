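---
title: "Random circuit perturbation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random circuit perturbation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racipe)
```

## The problem this package addresses

Mechanistic models of gene regulatory circuits are usually built around one
set of kinetic parameters, which is rarely known.  Random circuit
perturbation takes the opposite view: the robust, biologically meaningful
behaviours of a circuit are the ones that survive when *every* kinetic
parameter is randomized over a wide range.  The package therefore takes a
circuit topology — genes joined by activating (type 1) and inhibiting
(type 2) transcriptional links — as its only required input, generates an
ensemble of ordinary-differential-equation models with independently
randomized parameters, enumerates each model's stable steady states by
multi-start integration, and asks statistical questions of the pooled
result: which expression patterns recur (robust "gene states"), what each
gene contributes (in-silico knockouts), and how large the ensemble must be
for those statistics to converge.

## The model

Each gene $i$ follows

$$\frac{dX_i}{dt} \;=\; G_i \prod_{j \to i} F_{ji}(X_j) \;-\; k_i X_i,$$

where $G_i$ is the maximum production rate, $k_i$ the degradation rate,
and the product runs over the regulators of $i$, assumed independent
(non-competitive multivalent regulation).  Each regulatory factor is built
from the shifted Hill response
$H^S(X) = \lambda + (1-\lambda)\,H^-(X)$ with
$H^-(X) = 1/\bigl(1 + (X/X^0)^n\bigr)$:

* **inhibition**: $F = H^S$ with fold change $\lambda < 1$, falling from 1
  (no inhibitor) to $\lambda$;
* **activation**: $F = H^S/\lambda$ with $\lambda > 1$, rising from
  $1/\lambda$ (no activator) to 1.

The division by $\lambda$ for activation is forced by the meaning of
$G_i$: it is defined as the production rate with all activators, and no
inhibitor, bound — so the fully-activated factor must be 1, and the basal
rate without the activator is $G_i/\lambda$.  This choice is load-bearing:
with the un-normalized alternative ($F \in [1,\lambda]$), activated genes
in coupled circuits live on an entirely different concentration scale and
the downstream statistics change materially.  The exported
`shifted_hill()` is the plain response; `circuit_derivatives()` applies
the activation normalization.

## Randomization and the half-functional rule

Parameter ranges (`build_parameter_ranges()`):

| parameter | range | law |
|---|---|---|
| production $G$ | $[1, 100]$ (conc./time) | uniform |
| degradation $k$ | $[0.1, 1]$ (1/time) | uniform |
| Hill coefficient $n$ | $\{1,\dots,6\}$ | uniform integer |
| fold change, activation | $[1, 100]$ | uniform |
| fold change, inhibition | $1/\lambda \sim U[1,100]$ | reciprocal uniform |
| threshold $X^0$ | $(0.02\,M,\; 1.98\,M)$ | uniform |

The reciprocal law for inhibition makes strong and weak inhibition equally
represented on the $1/\lambda$ scale; most sampled inhibitions are strong
($\lambda < 0.1$ with probability $\approx 0.91$).

The threshold range is the one quantity estimated numerically, per
regulator, to satisfy the *half-functional rule*: each link should have
roughly a 50% chance that its regulator's level crosses the threshold
across the ensemble.  `estimate_threshold_range()` Monte-Carlo samples the
regulator's standalone level — $G/k$ times one independent regulatory
factor, uniform between its extremes, per incoming link of the regulator
(one level of context, no fixed-point self-consistency) — and centres the
threshold interval on the sample median $M$ with the symmetric window
$(0.02\,M, 1.98\,M)$.  The default 10,000 Monte-Carlo samples put the
median's relative error well below the window width; fewer than 1,000 is
rejected as too noisy.  The rule is validated behaviourally (the
single-link crossing fraction must land in $0.5 \pm 0.1$), not by
bit-identity to any particular implementation.

## Solving for stable states

Every model is integrated from `n_inits` initial conditions drawn
log-uniformly between each gene's extreme possible steady levels
($G/k$ times the product of extreme incoming factors), floored at a small
positive constant.  Integration (`solver_config()`) uses classical
Runge–Kutta with $dt = 0.1$ by default (first-order Euler with
$dt = 0.01$ is available); a start is converged when the largest per-gene
change in $\log_2$ level over a 50-time-unit window falls below
$10^{-3}$, with a 200-window cap.  Two points matter here:

* both solvers share the exact fixed points of the continuous system (a
  zero-derivative state is stationary under either discrete map), so the
  method choice affects cost and stability, not the steady states;
* a cheap derivative-based shortcut declares convergence when the current
  drift already satisfies the window criterion with two orders of
  magnitude of margin — it can only stop at states the windowed criterion
  would also accept (steady-state values agree with an adaptive
  reference integrator to ~1e-13 on linear problems).

Non-converged starts (including any limit cycles, which the tool does not
characterize) are counted and excluded.  Levels below $10^{-10}$ are
treated as exact zeros.  Distinct states are found by a greedy
first-occurrence scan: a state is new if its Euclidean distance in
$\log_2$ space to every kept state exceeds `dedup_tol = 1`.  On ensembles
of the circuits studied here the count of distinct states is insensitive
to this tolerance over 0.05–1.0 (attractors are well separated), and the
counts were verified to match `deSolve::lsoda` run from identical starts.

## Ensembles, seeding, and the paired perturbation design

`run_ensemble()` derives one child seed per model from the master seed
before anything else consumes randomness, so results are independent of
how the ranges were obtained and reproducible run-to-run.  Parameter
sampling consumes a fixed number of stream draws per parameter — including
degenerate ranges — so a knockout ensemble (production range pinned to
$[0,0]$ by `apply_perturbation()`) shares every untouched parameter draw
with its wild-type counterpart under the same seed.  Threshold ranges are
deliberately *not* re-estimated after a perturbation: the perturbed
ensemble is the same population of models under treatment, enabling
paired comparison.  Over/under-expression scales the production range
multiplicatively; link removal deletes the edge and its three parameters.

## Statistics over the ensemble

Pooled stable states (log2 levels, as in the `_solution_i.dat` files) are
z-scored per gene (`normalize_expressions()`); knockout data are
normalized with the wild-type centre and scale so the knocked-out gene
sits at its fixed "zero expression" coordinate, and are projected onto
the wild-type principal components (`racipe_pca()`, `project_states()`;
components are sign-fixed so each component's largest-magnitude loading
is positive).

**Clustering.**  Average-linkage clustering on Euclidean distances
(`hierarchical_clusters()`) reports the "major" clusters, those holding
at least 5% of all states.  Selecting the cut is the one genuinely open
design choice.  Maximizing the number of major clusters over *all* cut
heights is degenerate: average linkage splits even a single tight
Gaussian cluster into balanced halves that each stay above 5%, so the
unconstrained count grows with the cut size and two well-separated blobs
would report six "major clusters".  The rule used here selects by
*persistence*: cut sizes $k = 1..\lfloor 1/\text{cutoff} \rfloor$ (at a
5% cutoff, up to 20 — more major clusters than that are impossible) are
scanned, and the major-cluster count holding over the longest
consecutive stretch of $k$ wins, ties toward the earliest stretch,
cutting at the stretch's smallest $k$.  A persistent count means
additional cuts are absorbed by sub-5% fragments — the signature of real
separated patterns — whereas counts produced by splitting a genuine
pattern into balanced halves keep changing as $k$ grows.  On synthetic
two-blob data this yields the two planted clusters; on five-motif
coupled-toggle-switch ensembles it yields the six gene states whenever
each of the six holds at least 5% of the pooled states (at 2,000 models
an occasional seed leaves the rarest gene state just under the cutoff,
and five are reported).  The rule is deterministic.

**Convergence diagnostics.**  The headline distributions — the per-model
state-count distribution and per-gene binned expression histograms (50
equal-width bins spanning the reference range) — are compared between
replicate runs with the Bhattacharyya distance
$D_B = -\ln \sum_x \sqrt{p(x) q(x)}$ (Kullback–Leibler available as an
alternative), averaged over all replicate pairs between a test setting
and the largest setting (`replicate_dissimilarity()`, 10 replicates per
setting by convention).  Zero-overlap comparisons are capped at 700
($\approx -\ln$ of the smallest positive double).
`minimal_setting_scan()` reports the smallest setting beyond which the
dissimilarity decreases by less than $5 \times 10^{-4}$ per step.

**Parameter differentiation.**  For two gene states,
`parameter_differentiation()` contrasts the models contributing states to
each cluster, parameter by parameter: standardized mean difference,
Wilcoxon rank test, Benjamini–Hochberg adjustment across parameters.  In
toggle-switch ensembles the discriminating parameters between the two
monostable phenotypes are the inhibition thresholds and production rates
(the fold change saturates under reciprocal sampling and carries little
signal) — worth knowing before interpreting effect tables.

## What the generators emulate, and problem sizes

`topo_cts("I", n)` / `topo_cts("II", n)` build the coupled toggle-switch
benchmark family: $n$ mutually-inhibiting gene pairs chained by
unidirectional (I) or mutual (II) activations on each side, the standard
model of coupled binary cell-fate decisions.  They capture multistability
and cascade structure; they do not emulate self-activation,
post-transcriptional control, or noise — conclusions from passing tests
transfer to real circuits only insofar as those are
transcription-factor-only circuits of comparable size.

The package's own validation uses desk-scale ensembles chosen to keep the
full suite re-runnable interactively: CTS-I5 at 2,000 models × 200
initial conditions (the published analyses of this family used
10,000 × 1,000), knockouts at the same scale, the half-functional check
at 5,000 single-link models, and toggle-switch convergence scans over
10 replicates at up to 5,000 models with 10 starts each.  At 2,000 × 200 the
six major clusters and the high observed multistability (up to 7–8
coexisting states) are already reproduced; the mean number of states per
model is scale-stable but sits near 1.4 (see the limitations below).

## Known limitations

* **States per model.**  With strict convergence to attractors, CTS-I5
  ensembles average ~1.4–1.6 distinct stable states per model, robust to
  the deduplication tolerance, the number of starts, and both threshold
  recipes we examined.  Tools that integrate a fixed horizon and
  deduplicate the endpoints report materially higher counts at short
  horizons (we measure ~3.2 at $T = 50$, ~1.6 by $T = 100$), because slow
  starts are counted as extra states.  This package reports attractors
  only.
* Limit cycles are flagged as non-converged, not characterized.
* The threshold estimator uses one level of regulatory context; it is a
  declared construction validated by the half-functional property, not a
  reproduction of any specific implementation.
* Clustering granularity ultimately depends on the gap heuristic;
  pathological dendrograms with no clear gaps fall back toward coarse
  cuts.

## A short worked example

```{r example, eval = FALSE}
topo <- topo_cts("I", 2)
ens <- run_ensemble(topo, n_models = 500, n_inits = 100, seed = 1)
glance(ens)

z  <- normalize_expressions(expression_matrix(ens))
cl <- hierarchical_clusters(z)
tidy(cl)

autoplot(ens)               # PC1/PC2 density of the pooled states
plot_state_counts(ens)      # distribution of states per model

ko  <- apply_perturbation(topo, ens$ranges, perturbation("knockout", "A1"))
kod <- run_ensemble(topo, n_models = 500, n_inits = 100, seed = 1,
                    ranges = ko$ranges)
bhattacharyya(
  state_count_distribution(kod, max_count = 5),
  state_count_distribution(ens, max_count = 5)
)
```
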