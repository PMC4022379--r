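---
title: "Inferring gene regulatory networks as Boolean polynomial dynamical systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks as Boolean polynomial dynamical systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpds)
```

## The model

A Boolean network on $n$ genes is a map $f = (f_1, \dots, f_n) : \{0,1\}^n
\to \{0,1\}^n$, where each coordinate $f_i$ updates gene $i$ from the
current state of the whole network. Because $\{0,1\}$ with addition and
multiplication modulo 2 is the field GF(2), every Boolean rule can be
written as a polynomial: AND is the product, NOT $x$ is $x + 1$, XOR is the
sum, and OR$(x, y)$ is $x + y + xy$. Since $x^2 = x$ on $\{0,1\}$, each
polynomial can be reduced to *square-free* form (every variable appears
with exponent at most 1), and square-free polynomials over GF(2) correspond
one-to-one with Boolean functions. `bpds` represents a monomial by its
*support* (the set of variables appearing in it) and a polynomial by its
set of monomials; addition is the symmetric difference of monomial sets.

Dynamics are simulated synchronously: all coordinates are evaluated on the
same current state. Fixed points (steady states) do not depend on the
update schedule, so they are the dynamic predictions we emphasize;
`sequential_step()` exists to verify that schedule invariance, not as an
inference mode.

Knock-out and RNAi experiments are modelled by clamping the silenced
gene's coordinate to the zero polynomial ($f^* = (f_1, \dots, 0, \dots,
f_n)$, `knockout_model()`). Perturbation series are scored against the
clamped model; the data are taken as measured, with no clamping of the
observed columns.

## The restricted search space

The search space for each coordinate is a priori the $2^n$-dimensional
space of square-free polynomials. The package restricts it using an
interpolation-theoretic bound: a coordinate is constrained by the data at
exactly
$$m = \sum_{\mu} (\alpha_\mu - 1)$$
points, where $\alpha_\mu$ are the lengths of the input fragments (`total_length()`),
and a monomial $x^a$ can occur in a minimal interpolator of $m$ points only
if $\prod_i (a_i + 1) \le m$ — for square-free monomials, $2^{|\mathrm{supp}|}
\le m$, i.e. $|\mathrm{supp}| \le \Phi = \lfloor \log_2 m \rfloor$
(`support_bound()`, `is_admissible()`). The admissible monomial set has
dimension $\sum_{i=0}^{\Phi} \binom{n}{i}$ (`search_space_dimension()`),
a large reduction from $2^n$ already for moderate $n$. The bound is used
combinatorially — candidate polynomials are built directly from admissible
monomials — with no normal-form computation. When the maximum number of
regulator binding sites of a gene is known, a per-coordinate bound
$\Phi_i \le \Phi$ can be supplied through `search_space_spec()`.

## Data handling

Input series are binary matrices labelled wildtype or knock-out
(`time_series()`, `time_series_set()`). A deterministic model cannot
explain a state observed to transition to two different successors, so
before inference the data are *broken* at such inconsistencies: all
transitions out of an inconsistent state are removed (no successor is
preferred) and the affected series split into maximal consistent fragments
(`break_inconsistencies()`). Consistency is judged on pooled transitions —
all wildtype series together, each knock-out target separately — because a
single deterministic $f$ (or $f^*$) must explain the whole pool.

Continuous series are discretized per variable, either by quantiles
(thresholds at $j/s$ quantiles of the pooled values; `discretize_quantile()`)
or by equal-width intervals (`discretize_interval()`). Numerical
conventions, chosen once for determinism: quantile thresholds use R's
default (type 7) interpolation; values exactly at a threshold take the
lower level; constant columns discretize to all 0 with a warning. Binary
(`s = 2`) output feeds the inference engine; coarser discretizations exist
only for exporting data to external tools in meta-inference workflows.
Bit-flip noise at fraction $\xi$ is injected by flipping exactly
$\mathrm{round}(\xi \cdot \text{points} \cdot n)$ distinct positions
(round half up), seeded (`inject_noise()`).

## The fitness function

Inference is multi-objective; all components are in $[0, 1]$ and enter a
weighted sum (`total_fitness()`):

* **Model fit** (weight `w_hm`, default 1): each fragment is re-generated
  by free-running the candidate from the fragment's first observed state;
  $H_f$ is the total bit disagreement divided by $n \sum_\mu \alpha_\mu$.
  Knock-out fragments use the clamped model; wildtype and knock-out
  contributions combine by total bit count. The fit term is
  $w_{hm}(1 - H_f)$.
* **Coordinate fit** (weight `w_hp`, default 1): because updates are
  synchronous, the value of gene $i$ at time $t$ depends only on the
  observed state at $t - 1$, so each coordinate can be scored alone by
  one-step prediction; $H_{f_i}$ divides the mismatches in column $i$ by
  $\sum_\mu \alpha_\mu$. This is the signal that drives the
  divide-and-conquer search.
* **Complexity** (weight `w_c`, default 0.1): a coordinate's complexity is
  its total degree divided by $\Phi$; the model score is the coordinate
  average, entering as $w_c(1 - \text{complexity})$. The default weight is
  deliberately small: one degree step costs $1/\Phi$ (0.2 at $\Phi = 5$)
  while repairing a single data mismatch gains only about
  $1/\sum \alpha_\mu$ (about 0.02 on the default fixtures), so a large
  complexity weight makes constant rules dominate exact ones and the
  search can never reach a data-consistent model. At 0.1 the complexity
  term still decides between candidates of equal fit, which is its role:
  guarding against over-fitting without overruling the data.
* **Prior knowledge** (weights `w_b`, `w_re`, default 0.5): an $n \times n$
  matrix $\rho$ gives the probability that gene $j$ regulates gene $i$,
  from curated biology (`bio`) or from another inference method run on the
  same data (`reveng`, the meta-inference route). Agreement is
  $\beta_{ij} = \rho_{ij}$ if the model contains the edge and $1 -
  \rho_{ij}$ otherwise, averaged over entries; an uninformative prior
  ($\rho \equiv 0.5$) scores 0.5 for every model and so never moves the
  ranking.

The assumed noise fraction $\xi$ is a tolerance, not a target: any model
with $H_f \le \xi$ is flagged *data-consistent* (models are allowed to
disagree with the data commensurate with the expected noise), while the
fitness itself remains graded.

## The evolutionary search

The optimization exploits the coordinate decomposition with a two-tier
population:

* **Coordinate tier.** For each coordinate $i$ a persistent pool of
  candidate polynomials is kept (pool size = population size), ranked by
  $w_{hp}(1 - H_{f_i})$ plus the prior-row agreement and the complexity
  term. Every generation, half the pool is regenerated by mutating
  tournament-selected members — add, remove, or replace one monomial,
  staying inside the admissible set and a per-coordinate monomial cap —
  and the pool is re-ranked, so good coordinate candidates are never lost.
* **Model tier.** New models are assembled by $n$-point crossover: each
  coordinate is drawn from its pool by tournament. Assembled models are
  scored as wholes (free-run fit plus priors and complexity); the best
  `clone_fraction` are cloned unchanged into the next generation
  (elitism), the rest are mutated coordinate-wise at `mutation_rate`. The
  model population's coordinates feed back into the pools.

Monomial sampling favours sparse wiring: support sizes $k \ge 1$ carry
weight $2^{-k}$, and the constant monomial (needed for any NOT-containing
rule) draws the same weight as size 1. With a prior, variable choice is
weighted by $\max(\rho_{ij}, 0.05)$, so even edges the prior rules out
remain reachable.

A run stops when the generation cap is reached, or when the best model is
data-consistent ($H_f \le \xi$) and the best total fitness has improved by
less than $10^{-9}$ over 20 generations. Ranking ties are broken by lower
complexity, then by the lexicographic model text, so the output family and
the consensus edge-frequency matrix (`consensus_network()`) are fully
deterministic given the seed. One root seed drives every random choice;
identical inputs and seed give bit-identical results.

Latin hypercube sampling (`lhs_sample()`) generates parameter-set designs
for robustness studies: each parameter's range is split into equal strata
with one draw per stratum, permuted independently per parameter. Ranges
are user-supplied; weights (`w_*`) can be sampled alongside EA parameters.

## The synthetic fixtures

`fixture_spec()` + `random_model()` + `generate_series()` plant a known
model and emit its trajectories, so every claim the package makes can be
tested against a known truth without external data. The default condition
— used throughout the tests and the acceptance script — is a 5-node
network with in-degree at most 2 (1–2 monomials per rule, about half
negated), four wildtype and two knock-out series of 10 points each from
uniform random initial states. These sizes mirror the shape of published
time-course compendia (a couple of dozen points per gene across a handful
of perturbation series) while keeping a single inference run in seconds;
they give $m = 54$ transitions and $\Phi = 5$, so the planted rules are
comfortably inside the admissible space, and the generator refuses
specifications whose planted in-degree exceeds the bound of the data they
generate. What the fixtures do *not* emulate: dependent measurement noise,
discretization artefacts, unobserved regulators, and the long transients
of large state spaces — so passing these tests demonstrates correctness of
the machinery and recoverability under the stated conditions, not
performance on any particular biological compendium.

Three canned networks are included: `toggle3` (a 3-node negation ring with
no fixed points), `irma5` (a synthetic 5-gene, 8-edge circuit with a
feedback loop, shaped like the yeast IRMA benchmark network — the rules
are this package's own construction, not the biological system), and
`parasegment21` (a synthetic sparse 21-variable network shaped like a
one-parasegment segment-polarity system; structure only).

## A scale effect worth knowing about

On small networks, noise interacts destructively with inconsistency
breaking. With $n = 5$ there are only 32 states, trajectories reach a
fixed point $s^*$ within a few steps and then sit on it, and a single
flipped bit in any such tail makes $s^*$ itself inconsistent — upon which
the breaking rule deletes *every* $s^* \to s^*$ self-transition from the
pooled data. Measured on the default fixtures at $\xi = 0.05$: no planted
steady state keeps a single outgoing transition after breaking. The broken
data then carry no direct evidence of the fixed points, and an inferred
model retrieves them only through inductive bias (observed in roughly half
of seeded runs). On systems with large state spaces this collision
essentially never happens — corrupted rows are new states rather than
conflicting revisits — which is why steady-state retrieval under noise is
reported there. Treat small-$n$ retrieval-under-noise numbers accordingly.

## Numerical and design choices

* Monomials are sorted integer index vectors; polynomials carry a
  canonical key computed at construction, used for caching and
  deterministic tie-breaks. (Bit-mask supports were considered and
  rejected: portable R integers would cap $n$ at 31.)
* For $n \le 12$ the inner EA loop evaluates each distinct coordinate
  polynomial once on all $2^n$ states and then simulates by integer table
  lookup (XOR + popcount for mismatch counts); the path is exactly
  equivalent to direct evaluation and is cross-checked in the tests.
* Exhaustive steady-state enumeration is capped at $n = 20$; above that a
  sampling mode reports discovered fixed points flagged non-exhaustive.
* Reported PPV/recall are rounded half-up to 2 decimals alongside the raw
  fractions; a reversed edge counts as a false positive and its
  unrecovered true counterpart as a false negative; the negative universe
  is all ordered pairs excluding self-loops (switchable).
* $m$ is computed once, globally, over all fragments (wildtype and
  perturbation) after breaking; fragments of length 1 are retained but
  contribute nothing.
* Constant coordinate rules have empty support and therefore contribute no
  edges to inferred topologies.
* Problem sizes in the test-suite and acceptance experiments: 20 planted
  5-node fixtures per condition, population 60, at most 200 generations —
  sizes at which the full validation loop runs in minutes while leaving
  the EA enough budget to reach $H_f = 0$ on noiseless data in most runs.

## Known limitations

* Strictly binary dynamics; no multi-level or asynchronous fitting.
* The weighted-sum fitness has no Pareto-front machinery; incomparable
  trade-offs are resolved by the weights.
* The EA is a local search: on underdetermined data several models tie,
  and the family plus consensus matrix — not any single model — is the
  meaningful output.
* Default EA hyper-parameters and LHS ranges are this package's choices;
  they are exposed and meant to be overridden per data set.
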