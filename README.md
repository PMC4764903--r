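# dscent

Ranking the nodes of a network by how far an epidemic seeded at each one
will spread is a core task in network epidemiology and systems biology:
picking super-spreaders to immunize, proteins whose perturbation
propagates widely, or users who maximize diffusion. Purely topological
indices (degree, k-shell/coreness, eigenvector centrality) ignore that
the answer depends on the dynamics — a slow epidemic rewards dense local
neighbourhoods while a fast one rewards global position.

`dscent` implements the **dynamics-sensitive (DS) centrality**, which
folds the spreading rate β, the recovery rate μ and the time horizon *t*
of a discrete-time SIR/SI process into a walk-counting score. With
adjacency matrix **A**, propagation matrix **H** = β**A** + (1 − μ)**I**
and **L** the all-ones vector,

    S(t) = Σ_{r=1..t}  β A H^{r−1} L .

Interpretation: (β**A**H^{r−1}**L**)ᵢ linearly approximates the expected
number of infections node *i* generates at step *r*, so Sᵢ(t) is a
damped count of the walks leaving *i* — walks of length *r* weighted by
the probability the epidemic survives to traverse them. Limiting cases
built into the algebra (and tested):

* **t = 1**: S(1) = β·degree — the degree ranking exactly.
* **μ = 1** (one-shot SIR): S(t) = Σᵣ βʳ Aʳ L, a pure damped walk count.
* **β λ₁ + 1 − μ < 1** (below the epidemic threshold 1/λ₁, where λ₁ is
  the leading adjacency eigenvalue): S(t) converges to the closed-form
  limit β **A** (**I** − **H**)⁻¹ **L**.
* **β λ₁ + 1 − μ ≥ 1**, large *t*: the leading spectral mode dominates
  and the ranking converges to the eigenvector centrality **q**₁.

The package provides the iterative sparse implementation
(`ds_centrality()`), the spectral form (`ds_spectral()`), the
closed-form limit (`ds_centrality_limit()`), the linearized
per-node infection probabilities (`infection_probabilities()`), the
benchmark centralities (`degree_centrality()`, `kshell()`,
`eigenvector_centrality()`), a synchronous SIR/SI Monte-Carlo simulator
(`simulate_sir()`, `spreading_influence()`) with an exact enumeration
oracle for small graphs (`exact_expected_influence()`), Kendall tau-a
evaluation of rankings against simulated influence (`kendall_tau()`,
`accuracy_experiment()`), seeded fixture generators (`toy_graph()`,
`random_graph()`), plain-text edge-list I/O, and a CLI.

## Worked example

Score a 200-node Barabási–Albert network and check the ranking against
simulated ground truth:

```r
library(dscent)

net <- random_graph("ba", n = 200, m = 3, rng_seed = 1)
network_summary(net)
#> Network summary: n = 200, e = 594, <k> = 5.9400, lambda1 = 10.266832, 1/lambda1 = 0.097401

params <- spreading_params(beta = 0.05, mu = 1, t = 5)
S <- ds_centrality(net, params)
round(sort(S, decreasing = TRUE)[1:5], 4)
#>      6      2      3      5      4
#> 3.3308 2.9508 2.8236 2.5832 2.5055

# ground truth: mean SIR influence of every seed node (500 runs each)
infl <- influence_vector(net, params, n_runs = 500, rng_seed = 42)
kendall_tau(as.numeric(S), as.numeric(infl))
#> [1] 0.8114
kendall_tau(as.numeric(degree_centrality(net)), as.numeric(infl))
#> [1] 0.5948
kendall_tau(as.numeric(eigenvector_centrality(net)), as.numeric(infl))
#> [1] 0.7133
```

Node 6's DS score of 3.33 is its expected (linearized) count of
infections generated within 5 steps at β = 0.05; the tau values show the
DS ranking tracking the simulated influence ranking substantially better
than degree or eigenvector centrality at these dynamics.

The same computations are available from a shell:

```sh
Rscript inst/cli/dscent.R fixtures --family ba --n 200 --m 3 --rng-seed 1 -o net.edgelist
Rscript inst/cli/dscent.R summary net.edgelist
Rscript inst/cli/dscent.R centrality --method ds --beta 0.05 --mu 1 --t 5 net.edgelist -o scores.csv
Rscript inst/cli/dscent.R evaluate --beta-grid 0.01:0.10:0.01 --mu 1 --t 5 --runs 500 --rng-seed 1 net.edgelist -o table.csv
```

(After installation the wrapper lives at
`system.file("cli", "dscent.R", package = "dscent")`.)

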