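# threeoff2

Reconstruction of partially directed graphical models (CPDAG-like networks)
from finite tables of **categorical observations** — e.g. discretized
single-cell expression states of a panel of transcription factors — by the
*3off2* scheme: conditional 3-point information terms are iteratively
"taken off" each pairwise mutual information, in decreasing order of their
likelihood, until a structural independency is found or no contributor
remains. The surviving skeleton is then partially oriented by the ranked
likelihood of v-structures.

## The method in brief

For a pair `x, y` and candidate contributors `u_1, ..., u_n`, mutual
information decomposes exactly as

    I(x;y) = I(x;y;u_1) + I(x;y;u_2|u_1) + ... + I(x;y;u_n|{u_i}_{n-1})
             + I(x;y|{u_i}_n)

with `I(x;y;z|{u}) = I(x;y|{u}) - I(x;y|z,{u})` the conditional 3-point
information (symmetric in `x,y,z`; either sign). On `N` samples every
decision uses *shifted* information `I' = I - k/N` (2-point) and
`I' = I + k/N` (3-point), where `k` is a model-complexity term: MDL/BIC
(`½ (r_x-1)(r_y-1) Π r_u log N`) or, by default, the factorized
xy-symmetrized **normalized maximum likelihood** (NML) complexity built
from the universal multinomial constant `C^r_n` (exact binomial sum in log
space, Szpankowski expansion for large `n`, linear-time recursion in `r`).

A node `z` contributes to an edge with probability bounded by
`S_lb = min(P_nv, P_b)`, where `P_nv = 1/(1 + exp(-N·I'(x;y;z|{u})))` is
the probability the triple is *not* a collider and `P_b` is the softmax
probability that `xy` is the triple's weakest pair (its "base"). Edges are
processed by rank `R = max_z S_lb`; an edge is deleted when its shifted
conditional 2-point information turns negative, and its accumulated
contributors become the separation set. Unshielded triples are then swept
in decreasing `|I'(x;y;z|sepset)|`: negative triples orient as v-structures,
positive ones propagate arrowheads (Meek R1), conflicts are skipped in
favor of the more likely triple.

No significance level `α` is ever chosen: `N` itself sets the scale of
evidence.

## Worked example

Simulate a 4-node network with a collider (`x -> z <- y`) and a child
(`z -> w`), reconstruct it, and score the result against the ground truth:

```r
library(threeoff2)

net <- bn_fixture("collider_plus_child")
fit <- threeoff2(sample_bn(net, 5000, seed = 1))
tidy(fit)
#> # A tibble: 3 × 5
#>   from  to    mark      I2 I2_shifted
#>   <chr> <chr> <chr>  <dbl>      <dbl>
#> 1 x     z     ->    0.0279     0.0266
#> 2 y     z     ->    0.0293     0.0280
#> 3 z     w     ->    0.117      0.115

glance(fit)
#> # A tibble: 1 × 8
#>       n n_vars score rank_mode n_edges n_directed n_sepsets n_v_structures
#>   <int>  <int> <chr> <chr>       <int>      <int>     <int>          <int>
#> 1  5000      4 nml   shifted         3          3         3              1

evaluate_against_dag(fit$graph, bn_dag(net))
#> # A tibble: 1 × 11
#>      tp    fp    fn precision recall fscore ... tp_misorient precision_cpdag ...
#> 1     3     0     0         1      1      1 ...            0               1 ...
```

All three true edges are recovered (`fscore = 1`), the collider is oriented
from the negative 3-point information of the triple `(x, z, y)`, and the
`z -> w` arrow follows by propagation (`tp_misorient = 0`, so the
orientation-aware scores equal the skeleton scores). The `I2` column is the
final conditional mutual information of each pair in nats; `I2_shifted`
subtracts the NML complexity over `N`. On a chain fixture instead,
`I(x;y) ≈ 0.219` collapses to `I(x;y|z) ≈ 5e-5` once the middle node is
conditioned on, and the result is returned fully undirected — chain, fork
and reverse chain are Markov-equivalent, so no orientation is claimed.

`autoplot(fit)` draws the partially directed graph. A command-line
interface with the same functionality ships as `exec/threeoff2`
(`reconstruct | simulate | evaluate`).

## Scope

Complete-case categorical data only: no missing values, no continuous
variables or discretization, no latent-variable (bidirected-edge)
semantics. Orientation applies rules R0 and R1 only — R2/R3 enforce
acyclicity rather than a likelihood preference — so output PDAGs may
contain directed cycles. See the methods vignette
(`vignettes/threeoff2-methods.Rmd`) for the model, the finite-size
corrections, and the design decisions in full.
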