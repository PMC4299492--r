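---
title: "ebaflux: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ebaflux: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ebaflux` predicts bacterial gene expression and growth under genetic and
environmental perturbations by composing three layers: a linear
transcriptional model whose perturbation response is computed by Expression
Balance Analysis (a box-constrained quadratic program), an expression-gated
flux-bound modulation (TRAME) of a constraint-based metabolic model, and a
cost–benefit growth function. A greedy GO-coverage designer ranks candidate
knockouts, and seeded generators supply every input type with ground truth
so all claims are testable offline.

This vignette documents the modeling assumptions, the tunable parameters
with their defaults, the design decisions taken where the design was
genuinely open, what the synthetic generators do and do not emulate, and
the numerical machinery. It states no empirical result that the test suite
does not itself compute.

# The transcriptional model

Each gene's log2 expression is modeled at steady state as

$$y_i = \beta_{0,i} + \sum_{j \in R_i} \beta_{ij}\, y_j,$$

with $R_i$ the transcription factors (TFs) annotated as regulators of gene
$i$. Only the fixed point is modeled — the underlying mRNA dynamics are
linear ODEs, but every downstream use is a static optimization, so no time
integration is performed.

**Fitting.** Per gene, ridge-penalized least squares of $y_i$ on its
regulators across training arrays, with an unpenalized intercept
(regressors are centered before the penalty is applied). Arrays where the
gene itself is genetically perturbed are dropped for that gene only: its
equation is overridden there, so those rows carry no information about its
regulation. Environmental arrays are kept for all genes. With
`sign_constrained = TRUE`, coefficients on `+` edges are constrained
nonnegative and `-` edges nonpositive (solved as a bound-constrained least
squares with the package's box-QP solver); dual `+/-` edges are always
free, because curated networks record dual regulation without a resolution
rule. Whether the original regression was sign-constrained is not
determinable from the source material, so both modes are provided and the
unconstrained mode is the default.

**Degeneracy.** Collinear regulators are handled by a ridge floor of
$10^{-3}$ (applied, with a warning, to genes with fewer arrays than
regressors plus one), never by dropping edges.

**Capacity bounds.** `y_min`/`y_max` are the per-gene min/max over the
training compendium; `y_wt`/`sigma_wt` the mean/sd over wild-type arrays
(at least two are required).

# Expression Balance Analysis

Under a scenario, the genome-wide profile minimizes the squared slacks of
the TF equations subject to four constraint families:

* *phenomenological*: $\varepsilon_j = y_j - \beta_{0,j} - \sum_k \beta_{jk} y_k$
  for every TF $j$;
* *capacity*: $y_{\min} \le y \le y_{\max}$;
* *environmental*: effector-fixed TF values, via the signal-transduction
  layer;
* *genetic*: knockouts fixed at the floor, over-expressions at the
  ceiling, rewirings copying the donor's basal and regulatory
  coefficients.

The objective is $\varepsilon^\top H \varepsilon$ with $H$ defaulting to
the identity; the weighting is otherwise unspecified in the source
material, and an unweighted squared error is the neutral choice.

**Two-stage solve.** The QP runs over the TF subnetwork only, because the
objective sums TF slacks; imposing exact equality constraints on thousands
of non-TF genes together with hard capacity bounds would generically be
infeasible. Non-TF genes are then set to their linear prediction from the
optimal TF profile and clamped to their capacity bounds — the clamp *is*
the capacity constraint for the propagation stage. Fixed genes keep their
fixed values verbatim.

**Knockouts are expression-level by default.** A knocked-out TF is fixed
at its expression floor but its regulatory column stays active at that
floor value: the genetic constraint acts on expression, and a floor that
was observed in the compendium still represents residual transcript. A
`hard_knockout` flag zeroes the column instead for users who want
protein-absence semantics in the expression layer. (The metabolic layer
always treats knocked-out genes as absent enzymes; see TRAME below.)

**Infeasibility.** With slacks on every TF equation the QP is feasible
whenever the box is nonempty; degenerate boxes are repaired by the minimal
uniform relaxation and reported as `infeasible_relaxed`, never silently.

A property of the formulation worth knowing: because the objective couples
TF equations, the optimizer may shift a knocked-out TF's *regulators* to
reduce the knocked-out gene's own (unavoidable) equation slack. This is
inherent to minimizing total TF error and bounded by the capacity
constraints.

# Signal transduction

An effector either shifts a TF's expression or abolishes its activity.
Expression-type systems fix the TF at

$$\mathrm{clamp}\!\left(y_{wt} + \Omega\,\kappa\,\Delta n_E,\; y_{\min},\, y_{\max}\right),$$

where $\Delta n_E$ is the effector concentration change from the wild-type
reference, $\kappa$ (log2 expression per unit effector, sign = direction
of the response) is an empirical per-system parameter, and $\Omega$ is a
global fine-tuning scale. The calibration procedure for $\Omega$ is not
reproducible from the available material, so it is exposed as a
configuration scalar with default 1. Effector concentrations are treated
as abstract dimensionless quantities; $\kappa$ absorbs units. Multiple
effectors hitting one TF combine additively before a single clamp — the
model is declared linear. Mechanistic subtypes I–III collapse to the
sign/strength of $\kappa$; only the expression-vs-activity distinction
changes the math. Activity-only systems carry a binary rule
(functional with the effector present or not); a non-functional TF has its
regulatory column zeroed in the EBA layer while its own expression remains
a free variable.

# Metabolic layer and TRAME

FBA maximizes the biomass flux subject to $S v = 0$ and bounds; FVA
computes per-reaction flux ranges, optionally above a biomass fraction.
The FVA default is `biomass_fraction = 0`: TRAME needs the *physical
capacity envelope* of each reaction, not an optimum-conditioned range.

GPR rules evaluate enzyme availability with AND = min (complexes) and
OR = max (isozymes); OR = sum is available by flag for users who prefer
additive isozyme capacity.

**TRAME.** Per enzyme gene $e$, the relative expression ratio is

$$\rho_e = \begin{cases}
1 & |{\hat y}_e - y_{wt,e}| \le n\,\sigma_{wt,e} \\
2^{\,\hat y_e - y_{wt,e}} & \text{otherwise,}
\end{cases}$$

i.e. fold change gated by wild-type variability. Per reaction, the GPR
activity $a$ of these ratios passes through $P(a) = \min(a, p_{cap})$ and
scales the bound magnitudes: $v_{\max} \cdot P$ when $v_{\max} > 0$,
$v_{\min} \cdot P$ when $v_{\min} < 0$ — magnitudes scale, signs are
preserved, reactions without GPR are untouched. If a strictly positive
flux floor outruns a scaled-down ceiling, the floor is lowered to keep the
interval well-formed (a rescaled capacity cannot force flux the enzyme can
no longer carry).

The exact algebraic form of the original $P$-function is in unavailable
supplementary material; the gated fold-change with cap is a declared
surrogate honoring its stated dependencies (expression relative to wild
type; wild-type variability through $n$). Defaults: $n = 2$ standard
deviations, $p_{cap} = 10$.

Genes knocked out in a scenario are treated as **absent enzymes**
($\rho = 0$) in TRAME regardless of the expression-layer floor: a deleted
gene makes no protein. This is what makes single-path enzymes essential
and OR-redundant isozymes not.

**Essentiality.** A gene is essential when the full pipeline's predicted
growth under its knockout falls below 5% of the *unperturbed strain's
growth in the same environment* (exchange overrides and effectors applied
to both); infeasibility counts as essential.

# Cost–benefit growth

$$c = \gamma \cdot \frac{1}{N_G} \sum_i \frac{|\hat y_i - y_{wt,i}|}{y_{\max,i} - y_{\min,i}},
\qquad B = \frac{\text{FBA growth under TRAME bounds}}{\text{WT growth, reference environment}},
\qquad \mu = \max(0,\, B - c).$$

Genes with zero dynamic range are skipped ($N_G$ decremented). All units
are WT-relative so cost and benefit are commensurable; the original
absolute-unit bookkeeping is not recoverable from the elided equations,
and $\gamma$ (default 1) stands in for the fitted cost scaling. Negative
$B - c$ is reported as $\mu = 0$ with a diagnostic — the model predicts
no growth, not death dynamics. The cost is anchored at the *observed*
wild-type profile, so on a model fitted to noisy data the wild-type
scenario carries a small positive cost (the fitted fixed point is not
exactly the observed mean); on a self-consistent (noise-free) fit the
wild-type invariants $c = 0$, $B = \mu = 1$ hold exactly, and the test
suite asserts them there.

# Evaluation protocol

Per predicted array: global PCC over all genes; local PCC over the
radius-2 *downstream* neighborhood of the perturbed genes (regulatory
ripple effects propagate along edge direction; an undirected option
exists). Significance is empirical: the null distribution is the PCC of
`n_null` compendium columns (drawn with replacement, excluding the
evaluated array) against the measurement, with add-one smoothing
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{null})$ so $p$ is
never zero. A local p-value against the same null restricted to the
neighborhood is reported separately, since whether the original "local"
significance reused the global null is indeterminate. The summary
threshold TH is the mean global PCC over records, with *strict* inequality
— ties count below. Neighborhoods smaller than 3 genes flag the local PCC
as undefined rather than reporting a meaningless correlation.

# Experiment design

Eligible GO terms satisfy a level filter (default $\le 5$) and a gene-set
size window (defaults 3–500); these concretize the two coverage
constraints whose original definition is unavailable. A term is covered
when at least $k$ (default 1) of its genes are perturbed. The greedy
ranking maximizes marginal newly-covered terms, breaking ties by a
variability score — the mean expression variance of the candidate's
radius-2 downstream neighborhood (the candidate excluded; its own variance
as fallback) — then lexicographic id, so reruns are identical. When no
candidate covers anything new, the remaining budget is filled in
variability order. The neighborhood-variance score is a declared surrogate
for the original variability heuristic; genetic-only / environmental-only
/ combined variants are exposed as compendium class filters. Greedy
maximization of the monotone submodular coverage function carries the
usual $(1 - 1/e)$ guarantee, which the acceptance suite checks against
exhaustive search.

# The synthetic world

The generators state one world and the tests live in it:

* **Network**: TF out-degrees by preferential attachment (heavy-tailed,
  matching the scale-free character of bacterial regulatory networks);
  signs `+` with probability 0.6, 5% dual; coefficient magnitudes
  log-normal(meanlog −1, sdlog 0.5), rescaled so the TF-subnetwork
  spectral radius stays below 0.9 (stable fixed point); basal coefficients
  chosen so the wild-type fixed point sits mid-range (uniform on log2
  5–9 within the global 0–14 microarray-like scale).
* **Compendium**: per array, the exact linear fixed point plus Gaussian
  input noise, with scenario overrides (knockout → floor 0,
  over-expression → ceiling 14, effector → shifted TF), clamped to
  [0, 14].
* **Metabolism**: substrate uptake (capacity 10) feeding a linear enzyme
  chain into a biomass drain, with OR-redundant isozyme branches on one
  step; enzyme genes are drawn from the network's non-TF genes (preferring
  regulated ones) so the layers connect. Optimal growth and the
  essential/non-essential split are recorded analytically.
* **Signal transduction**: $\kappa$ log-uniform in magnitude on
  [0.1, 2] with random signs; 20% activity-only entries.
* **Scenarios with growth truth**: a mixture of enzyme knockouts,
  TF knockouts/over-expressions (preferring TFs within two regulatory hops
  of an enzyme), graded effector shifts, and nutrient
  abundance/limitation scenarios that vary the uptake bound — mirroring
  random-environment simulations over carbon abundance and limitation.
  The nutrient class is what makes the scenario set span the growth range
  instead of collapsing onto the all-or-nothing extremes; a recovery
  experiment with a degenerate response distribution would test only the
  noise. True growth is $B - c$ computed on the ground-truth coefficients
  plus Gaussian observation noise.

**Choice of recovery regime.** Exact coefficient recovery is asserted on a
noise-free world with smaller coefficient magnitudes (meanlog −1.8): exact
recovery requires the perturbed steady states to stay inside the clamp
range, since a saturated observation breaks the linear relation the
regression assumes. This is a property of any clamped linear world, not of
the implementation; the default (larger) magnitudes are used everywhere
else, where exactness is not claimed. Seeds are fixed arbitrary integers
threaded through a counter-based splitting scheme (`split_seed`) so every
artifact is independently regenerable bit-identically.

**What a green test does not establish.** The generators emulate the
*statistical structure* the framework assumes — steady-state linearity,
signed sparse regulation, WT replicate variability, GPR redundancy — not
biological content: no operons, no probe-level noise, no growth-dependent
global expression scaling, no realistic regulon sizes. Passing tests
certify the machinery (optimization, propagation, calibration, coverage
bounds), not organism-level predictive accuracy, which in the original
study required curated compendia and strain collections that are out of
scope here.

# Numerical choices

* **LP**: dense two-phase simplex with Bland's rule — deterministic and
  cycle-free; infinite bounds truncated to ±10⁴. Alternate-optima flux
  vectors are not canonicalized; only objective values are
  contract-bearing. Suitable for the toy-scale models this package
  targets (tens of reactions), not genome-scale models.
* **QP**: the box-constrained convex program is solved by cyclic
  coordinate descent (closed-form clamped updates, fixed sweep order)
  followed by an active-set Newton polish on the identified face;
  deterministic, no random initialization, warm-started at the clamped
  wild-type profile. Degenerate (zero-curvature) coordinates fall back to
  the sign of the gradient.
* **Tolerances**: EBA solve tolerance 10⁻⁸; LP pivot tolerance 10⁻⁹;
  steady-state and bound checks at 10⁻⁶.
* **Determinism**: identical inputs give bit-identical outputs end to end
  (asserted for solve–resolve and for the full simulate→train→predict
  CLI chain). All randomness flows through a single integer seed.
* **Ties**: greedy design breaks ties by variability then lexicographic
  id; duplicate network edges merge with the best evidence tier and `+/-`
  on sign conflict; TH comparisons are strict.

# Known limitations

* The simplex is dense and unsuited to genome-scale stoichiometries.
* The P-function, the Ω calibration, the cost normalization and the
  variability heuristic are declared surrogates for procedures whose
  exact forms are in unavailable supplementary material; each honors the
  stated dependencies and is flagged at its definition.
* Expression-layer knockouts retain floor-level regulatory activity by
  default (see above); users wanting strict protein-absence semantics in
  the expression layer should set `hard_knockout`.
* No time courses, no stochastic single-cell effects, no thermodynamic or
  macromolecular-crowding constraints.
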