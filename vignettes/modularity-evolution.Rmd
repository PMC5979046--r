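---
title: "Sparseness, selection for additional phenotypes, and the evolution of modular gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparseness, selection for additional phenotypes, and the evolution of modular gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnmod)
```

## The question

Gene regulatory networks tend to be modular — their interactions concentrate
within groups of genes — and they tend to be sparse. Whether sparseness
*explains* modularity, is *necessary* for it, or merely *amplifies* other
causes is the question this package is built to interrogate. It provides the
three ingredients needed to do so quantitatively:

1. a discrete model of the developmental dynamics a gene network generates;
2. an evolutionary engine that subjects populations of networks to mutation
   and selection for producing one or more gene activity phenotypes; and
3. a directed-network modularity toolkit whose z-score normalization against
   degree-preserving null models removes exactly the contribution that
   sparseness alone makes to raw modularity scores.

## The developmental model

A network of `N` genes is a signed `N x N` matrix `G`; `g_ij > 0` means gene
`j` activates gene `i`, `g_ij < 0` that it inhibits it. States are binary
vectors (gene on/off), updated synchronously:

* gene `i` turns on when `sum_j g_ij s_j > theta_i`,
* turns off when the sum is below `theta_i`,
* and holds its state on an exact tie.

The threshold is `theta_i = (sum_j g_ij) / 2`, half the row sum. With this
choice the model is exactly the classic Wagner model: mapping states
`s in {0,1}` to `sigma = 2s - 1` turns the update into
`sigma' = sign(G sigma)` with ties holding. The package asserts this
equivalence exhaustively in its test suite; it is the reason half-row-sum is
the default rather than, say, a fixed threshold. A `"zero"` threshold
variant (`theta_i = 0`) is available as a robustness check, as is a
continuous-weight genotype mode; both change dynamical details while
leaving the modularity questions posed to the model intact.

Iterating the update from an initial state must revisit a state within
`2^N` steps; from there the trajectory cycles through `k` distinct states.
That terminal cycle is the network's *gene activity phenotype* (GAP): a
fixed point when `k = 1`, a limit cycle otherwise. `grn_develop()` returns
it together with the transient length, and an internal cap of `2^N + 1`
iterations turns any bookkeeping bug into a loud failure instead of a hang.

```{r dynamics}
g <- grn_genotype(rbind(c(0, 1), c(1, 0)))  # mutual activation
grn_develop(g, c(1, 0))                      # a 2-cycle GAP
```

## Fitness, mutation, selection

An organism is a bag of 100 cells. With `T` target GAPs, `K = 100/T` cells
must produce each target; each cell starts from the target pattern with
every gene flipped independently with probability `kappa` (developmental
noise), develops to its GAP, and contributes `(1 - S)^D` to its target's
score, where `D` is the Hamming distance to the target for stationary GAPs
and the mean Hamming distance over cycle states otherwise. A target's
contribution is the mean over its cells; organismal fitness is the product
over targets. The distance rule for cyclic phenotypes is a design choice of
this package (the model family only fixes the stationary case); it reduces
correctly for fixed points, penalizes oscillation around a stationary
target, and is exposed as a pluggable function for sensitivity analyses.

Mutation acts per gene. With `R_i` current regulators out of `N`, a gene
loses a uniformly chosen interaction with probability
`mu (1 - gamma) R_i / N` and gains one (random sign) with probability
`mu gamma (N - R_i) / N`; the events are mutually exclusive within one
generation, keeping the per-gene mutation probability bounded by `mu`.
Detailed balance of these rates pulls regulator counts toward `gamma * N`,
so the expected network density is `gamma * N^2` — `gamma` is the model's
sparseness dial. An unbiased variant (gain/loss coin flip at rate `mu`) and
a continuous-weight variant (standard-normal weights; redraws preserve
sign) cover the robustness scenarios.

Generations are fitness evaluation, roulette-wheel selection of `M` parents
with replacement, and mutation of every offspring. Populations are founded
by `M` copies of a random network with `round(gamma * N^2)` interactions
for which the ancestral target is a fixed point (`build_founder()` rejects
candidates until one qualifies). Selection regimes are expressed as
consecutive *stages*, each with its own targets and optional `gamma`/`kappa`
overrides; the evolved population carries over between stages, because the
questions of interest compare the same lineages before and after a change
in conditions.

Reference parameter values, used as defaults throughout: `N = 10`,
`M = 200`, `mu = 0.01`, `gamma = 0.3`, `kappa = 0.05`, `S = 0.4`.

## Measuring modularity

For a directed graph with `L` edges and a partition `P` of its nodes,

    Q_P = sum_m [ l_m / L  -  d_in(m) d_out(m) / L^2 ]

compares the fraction of edges internal to each module with the expectation
for random graphs of the same degrees. With no partition hypothesis,
`spectral_partition()` searches for the best one: recursive spectral
bisection on the symmetrized directed modularity matrix, Kernighan–Lin-style
fine tuning (single-node moves, best first, accepted while they gain
modularity), recursion stopping when a split no longer helps. Every
tie-break is deterministic — eigenvector sign fixed by its first nonzero
entry, zero entries assigned to the positive side, moves tied on gain going
to the lowest node index — so results are pure functions of the graph.

Raw scores inflate in sparse graphs: random fluctuations in local edge
density create apparent modules more easily when edges are few. The study's
central methodological point is to remove this with a z-score against
degree-preserving nulls: `Q_P^N` (and `Q^N` for the optimized score) is the
number of null-ensemble standard deviations by which the focal network's
score exceeds the ensemble mean, over (by default) 1,000 randomizations of
the "switching" kind — repeated two-edge rewires `(a->b),(c->d)` to
`(a->d),(c->b)` that preserve every in- and out-degree exactly, rejecting
duplicates and new self-loops. We attempt `100 * L` swaps per
randomization, standard practice for this sampler. Degenerate null
ensembles (zero spread) yield `NA` with a warning, never a silent 0.

```{r modularity}
planted <- grn_digraph(4, rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3)))
spectral_partition(planted)
```

### Calibration choices

Two choices were genuinely open and were settled by calibration against the
model family's published ensemble behaviour:

* **Self-loops in random ensembles.** Autoregulation is a legitimate entry
  of the genotype matrix, so `random_digraph()` allows self-loops by
  default. This is not cosmetic: 10-node, 20-edge ensembles *without*
  self-loops have a mean optimized modularity of about 0.22 (their
  exhaustive-best partitions average 0.226, so no optimizer could score
  higher), while ensembles *with* self-loops average about 0.28 with the
  expected density contrast and KS separation — the regime the reference
  ensemble statistics describe. Fixed-partition score spreads match only
  under the same convention.
* **Existing self-loops under randomization.** The switching move cannot
  relocate a self-loop without breaking a degree sequence, so self-loops
  are frozen in place and excluded from the swappable pool; no new ones are
  created.

## The experiment layer

`run_two_stage()` is the central scenario: an ancestral stage selecting for
one stationary target GAP, then a second stage selecting simultaneously for
the ancestral target and a new one differing in `n_differing` gene states
(five by default, giving equal "same" and "differing" gene sets A and B).
The partition `{A, B}` is the mechanistic module hypothesis, and the
headline measurement is the focal network's `Q_P^N` against it at each
stage end. Analyses default to the adapted-populations protocol — keep
populations whose maximum fitness exceeds 0.9, sample one top-fitness
network each — with alternatives keeping every population or averaging over
population members. `run_gamma_sweep()`, `run_kappa_sweep()` and
`run_epoch_switch()` vary sparseness and noise around this scenario;
`analyze_empirical_network()` applies the `Q^N` machinery to any TSV edge
list.

The default target pair puts the ancestral target at "all genes active";
only the *number* of differing genes matters in this model family, so the
generator can also draw random target pairs with the same difference
structure (`fixed = FALSE`) without changing any statistical conclusion.

## Problem sizes, reproducibility, and what the tests show

The study's full scale (500 populations, 10^4–2x10^4 generations each) is
cluster-sized. The package's own acceptance checks run desk-scale versions
chosen for statistical adequacy: full-size random ensembles (3,000
networks; these are cheap), 10–30 populations for the evolutionary
scenarios at the original generation counts for the two-stage experiment,
and proportionally shortened epochs (2,500–5,000 generations each) for the
epoch-switch designs. At these sizes, means of per-population z-scores
carry standard errors around 0.2–0.3, so scaled-down reproductions are
compared at roughly two standard errors; direction and ordering claims
(e.g. "modularity gain shrinks as `gamma` grows") use replicate counts
power-checked during design to make sign errors unlikely. One caveat of
shortened epochs: states that the full-scale study measures at
equilibrium (e.g. the anti-modular drift of optimized modularity under
single-phenotype selection) are still relaxing from the founder's
z-score of roughly zero, so their desk-scale means sit between 0 and the
full-scale value and are judged with an explicit sampling allowance.

Attractor memoization per (genotype, initial state) makes the 10^4
generation runs tractable; a dedicated test asserts that cached and
uncached engines produce bit-identical traces on a fixed seed. All
randomness — including inside the C++ engine — draws from R's RNG, so
`set.seed()` makes every run exactly reproducible. Inside the engine,
perturbed initial states are sampled by drawing a Binomial(`N`, `kappa`)
flip count and then distinct flip positions, which is distributionally
identical to independent per-bit flips but substantially faster at small
`kappa`.

What passing tests do *not* show: the synthetic scenarios use equal-sized
or fixed-ratio gene sets, targets that are exactly stationary, and
selection pressures constant within a stage. Real regulatory networks have
unbalanced modules, noisy and context-dependent phenotypes, and selection
regimes that drift; the empirical-network analysis (`Q^N` on measured edge
lists) is therefore the only part of the package that speaks directly about
real networks, and it only says whether a network out-scores its
degree-matched nulls, not why.

## Known limitations

* The engine packs states into machine words: `N <= 31` genes (the
  scenarios here use 10–16).
* Spectral optimization with fine tuning is a heuristic; the test suite
  asserts it never exceeds, and on average trails by less than 0.05, the
  exhaustive best partition on 8-node graphs, but it can return locally
  optimal partitions on larger graphs, as all practical modularity
  optimizers do.
* `Q_P^N` depends on the partition hypothesis; it is a test of a specific
  mechanistic prediction, not a general modularity measure.
* Gene duplication, recombination and cis-regulatory sequence evolution are
  outside the model.
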