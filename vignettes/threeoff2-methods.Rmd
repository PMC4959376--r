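---
title: "Reconstructing partially directed networks by taking 3-point information off 2-point information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing partially directed networks by taking 3-point information off 2-point information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threeoff2)
```

## The problem

Given a table of categorical observations — samples in rows, variables in
columns, think single-cell expression states of a handful of transcription
factors — we want the graphical model that generated them: which pairs of
variables are directly coupled, and, where the data permit, in which causal
direction. Constraint-based algorithms (PC/IC) answer this by hunting for
conditional independencies at a user-chosen significance level $\alpha$, and
are notoriously brittle on finite samples: one early false deletion cascades
into compensatory errors. Score-based Bayesian searches are robust but must
explore a super-exponential space of DAGs.

`threeoff2` implements a hybrid scheme that keeps the constraint-based
skeleton/orientation structure but replaces the independence tests with
ranked maximum-likelihood decisions. Its central identity decomposes any
mutual information along candidate contributor nodes $u_1, \dots, u_n$:

$$
I(x;y) \;=\; I(x;y;u_1) \;+\; I(x;y;u_2\,|\,u_1) \;+\; \cdots \;+\;
I(x;y;u_n\,|\,\{u_i\}_{n-1}) \;+\; I(x;y\,|\,\{u_i\}_n),
$$

where $I(x;y;z\,|\,\{u\}) = I(x;y\,|\,\{u\}) - I(x;y\,|\,z,\{u\})$ is the
conditional 3-point information. The algorithm iteratively *takes off* the
most likely positive 3-point term from each pair's 2-point information; an
edge is deleted once the remainder drops below its complexity cost, and the
accumulated contributors form the pair's separation set.

## Finite-size corrections

On $N$ samples, "independence" cannot mean $I = 0$; it means the simpler
model is more likely once the cost of parameters is paid. All decisions
therefore use *shifted* information,

$$
I'(x;y\,|\,\{u\}) = I(x;y\,|\,\{u\}) - \frac{k_{x;y|\{u\}}}{N},
\qquad
I'(x;y;z\,|\,\{u\}) = I(x;y;z\,|\,\{u\}) + \frac{k_{x;y;z|\{u\}}}{N},
$$

with two interchangeable complexity terms:

* **MDL/BIC**: $k^{\mathrm{MDL}}_{x;y|\{u\}} = \tfrac12 (r_x-1)(r_y-1)
  \prod_i r_{u_i} \log N$, the asymptotic (Laplace) limit — cheap, but it
  overestimates the cost of edges between many-level variables at realistic
  $N$, because most of the $(r_x-1)(r_y-1)\prod r_u$ parameter combinations
  are never sampled.
* **NML** (default): the factorized, xy-symmetrized normalized-maximum-
  likelihood complexity, built from the universal multinomial constant
  $\mathcal{C}^r_n$. Only observed parent states contribute
  ($\mathcal{C}^r_0 = 1$), which is exactly what repairs the MDL bias.

$\mathcal{C}^2_n$ is evaluated by its exact binomial sum in log space up to
$n^* = 1000$ (configurable) and by the Szpankowski asymptotic expansion
beyond — the expansion's relative error is already below $10^{-6}$ there,
and the exact sum costs $O(n)$ per call; higher $r$ follow the linear-time
recursion $\mathcal{C}^r_n = \mathcal{C}^{r-1}_n + \tfrac{n}{r-2}
\mathcal{C}^{r-2}_n$. All values are memoized: NML sums revisit the same
$(n, r)$ pairs constantly.

A negative $I'(x;y;z\,|\,\{u\})$ means a collider (v-structure)
$x \to z \leftarrow y$ is more likely than the Markov-equivalent chain/fork
alternatives; a positive value the converse. This sign rule, plus the
observation that the most likely *base* of a triple is its weakest pair
(consistent with the Data Processing Inequality), yields two probabilities
computed in the log domain:

$$
P_{nv} = \frac{1}{1 + e^{-N I'(x;y;z|\{u\})}}, \qquad
P_b(xy) = \mathrm{softmax}_{\,xy,\,xz,\,yz}\!\left(-N I'(\cdot\,|\,\{u\})\right),
$$

combined conservatively as $S_{lb} = \min(P_{nv}, P_b)$ — both conditions
must hold for $z$ to be a genuine indirect contributor to the $x$–$y$
dependence.

## The two steps

**Skeleton.** Start from the complete graph; drop pairs with
$I'(x;y) < 0$ outright (empty separation set), and isolate variables with a
single observed level (they carry no information and zero complexity, so no
strict test could ever remove them). Each surviving edge holds a candidate
set — the current neighbors of its endpoints — and a best contributor; edges
are processed in decreasing rank $R = \max_z S_{lb}$. Accepting a
contributor strictly lowers the shifted 2-point information; when it turns
negative the edge is removed and its contributors recorded as the
separation set. Candidate ranks are recomputed lazily when a removal changes
a neighborhood.

Two ordering details matter in practice:

* *Tie-breaking.* At large $N$ every plausible contributor saturates at
  $S_{lb} = 1$ in double precision, so ties are the rule. They resolve by
  the larger (shifted) 3-point contribution — taking off the maximum
  contribution minimizes the remaining 2-point information, which is the
  scheme's own objective — then lexicographically by name. Breaking ties
  purely by name can condition on a collider's child before the true
  mediator, permanently re-opening that path.
* *Local trapping.* The take-off is greedy and monotone: a contributor,
  once accepted, is never retracted. A confounded common child can present
  a positive 3-point contribution and a satisfied base condition *before*
  the confounders are conditioned away; accepting it re-opens the collider
  path and the edge can no longer be removed. On random 8-node benchmarks
  this leaves roughly one spurious edge in ~5% of runs. A stochastic
  variant that samples among significant contributors instead of always
  taking the best one is the natural remedy and deliberately out of scope
  here.

With the MDL score the recommended (`rank = "auto"`) pairing ranks
contributors and triples by *raw* information while still testing removals
with the shifted criterion: MDL's overestimated complexities otherwise
produce early false deletions, and errors in a raw-ranked conditioning set
can only leave $I(x;y\,|\,\{u\}) \ge 0$, which is the safer failure. We
apply the chosen mode uniformly to both probabilities in $S_{lb}$.

**Orientation.** Unshielded triples $x - z - y$ are scored by
$I'(x;y;z \,|\, \mathrm{sepset}(x,y) \setminus z)$ — the separation set is
the step-1 estimate of the upstream contributors, and $z$ is excluded so it
cannot zero its own term — and swept in decreasing $|I'|$ (ties:
lexicographic on $(z, x, y)$). Negative triples orient as v-structures;
positive triples propagate an existing arrowhead through $z$ (Meek's R1).
Conflicting claims are *skipped*, never overwritten: the less likely triple
is ignored along with its propagations. Sweeps repeat until a pass changes
nothing; triple scores are computed once from step-1 separation sets
(static scores, dynamic sweep — re-scoring after each orientation is a
defensible alternative we did not take, as the separation sets do not change
during orientation). Rules R2/R3 are deliberately not applied: they enforce
acyclicity rather than express a likelihood preference, so the output may
in principle contain directed cycles. Triples with $I' = 0$ exactly are
never used.

For *evaluation* the package does apply full Meek closure (R1–R3), but only
to convert a known ground-truth DAG into its reference CPDAG
(`cpdag_of_dag()`), verified in the tests against exhaustive enumeration of
each equivalence class.

## What the simulator emulates — and what it does not

`bayes_net()` / `sample_bn()` perform ancestral sampling from discrete
Bayesian networks; `random_bn()` draws benchmark-style DAGs (uniform random
topological order, target average degree, bounded in-degree) with either
symmetric-Dirichlet CPT rows ($\alpha = 0.5$ by default; sparse enough to
be identifiable, but individual rows can still come out near-uniform) or a
deterministic strong-dependence scheme (`cpt = "strong"`: 0.85 of the mass
on a preferred level grading with the mean parent level).

The named fixtures (`bn_fixture()`) are hand-set, not random, so their
independencies hold *exactly*: roots are genuinely independent, chains are
genuinely Markov. Their collider CPT deserves a note. A symmetric XOR —
the obvious choice for a "strong" collider — makes each parent marginally
independent of the child, so no observational method could keep those
edges; and any binary collider CPT with $P(1|0,0) = P(1|1,1)$ creates an
exactly *unfaithful* cancellation two generations down in the 8-node
mini-benchmark (a grandparent becomes marginally independent of the
collider, which manufactures a spurious v-structure). The fixtures
therefore use a leaky AND gate, $P(1 \mid 00, 10, 01, 11) =
(0.30, 0.03, 0.03, 0.97)$, chosen by maximizing the weakest information
term the reconstruction relies on over the *exact* joint distribution:
every required dependence stays above 0.065 nats in isolation and above
0.092 nats inside the mini-benchmark.

Passing tests on these fixtures show the machinery is correct under
faithful, complete-case, amply-sampled categorical data. They do not show
robustness to the things real single-cell data adds: dropout and missing
values, continuous expression requiring discretization, latent confounders,
or selection effects. All four are explicitly out of scope.

## Numerical and design choices

* All information is in **nats** (natural log); the log base is never mixed
  with the complexity terms. Division by `log(2)` converts to bits.
* Entropies come from sparse observed-state tables; $0 \log 0 = 0$; tiny
  negative conditional MI from floating-point cancellation is clamped to 0.
* Every exponential of $\pm N I$ goes through `plogis` or log-sum-exp.
* Categories are integer-coded in lexicographic label order, and levels
  $r_v$ count *observed* categories only — unobserved theoretical levels are
  ignored, matching the plug-in estimators. Missing cells are rejected, not
  imputed.
* The removal test is strict ($I' < 0$), and `max_cond_size` (default
  unbounded) can cap separation-set growth on dense problems.
* Problem sizes in the test-suite and the acceptance script — 20 sampling
  seeds at $N = 50{,}000$ for the fixtures, 10 seeds at
  $N \in \{100, 1000, 10000\}$ for the mini-benchmark, brute-force
  enumeration up to $n = 12$, $r = 5$ — were chosen to exercise every
  asymptotic regime while keeping a full run in minutes on one core.

## A worked run

```{r example}
net <- bn_fixture("collider_plus_child")
bn_dag(net)

fit <- threeoff2(sample_bn(net, 5000, seed = 1))
tidy(fit)
glance(fit)

evaluate_against_dag(fit$graph, bn_dag(net))
```

The collider `x -> z <- y` is identified from the sign of the triple's
3-point information, and R1 propagates `z -> w` (undirecting it would
create a new v-structure). Chains and forks, being Markov-equivalent to
each other, correctly come back fully undirected.

## Known limitations

* Greedy local trapping (above): ~5% of random 8-node runs keep one
  spurious edge at $N = 50{,}000$.
* Complete cases only; categorical only.
* No latent-variable (bidirected-edge) semantics; output PDAGs may contain
  directed cycles because R2/R3 are not enforced.
* The NML score is evaluated per candidate conditioning set; on dense
  graphs with many levels this is the computational bottleneck, mitigated
  by memoizing $\log \mathcal{C}^r_n$ and per-run entropy caches.
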