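---
title: "Inferring ancestral gene complements from dated trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestral gene complements from dated trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronopsin)
```

## The problem

Gene families expand by duplication, and extinct lineages cannot be genotyped.
When both the gene family and the species phylogeny have been dated with
Bayesian relaxed clocks, each duplication and each speciation carries a 95%
credibility interval (CI) on its age, in Ma before present. Comparing the two
chronologies tells us which paralogues could already have existed when a stem
lineage -- say, the lineage leading to a Cambrian fossil -- split from the
line of descent on which the duplications accumulated. chronopsin implements
this molecular-palaeobiological inference for any dated gene family, with the
ecdysozoan visual opsins (the gene family behind arthropod colour vision) as
its worked example.

## The interval-comparison rule

The core primitive is `precedes(dup, div)`. A duplication with CI
$(d_y, d_o)$ is judged to precede a species divergence with CI $(s_y, s_o)$
**iff** $s_o < d_y$ strictly: the divergence interval must lie entirely on
the younger side of the duplication interval. Touching endpoints count as
overlap. Any overlap returns `ambiguous`, and an ambiguous event is resolved
conservatively: the descendant lineages are assumed to have inherited the
single ancestral gene, not the paralogue pair. Consequently every inferred
complement is a *minimal* estimate -- widening either interval can only
shrink it, never grow it (this monotonicity is enforced by property tests).

`infer_complement()` applies the rule as a frontier cut on the dated
duplication tree: starting from the root gene, a gene is expanded into its
two daughters only when its duplication precedes the divergence; the
unexpanded frontier is the complement. A daughter duplication is only
examined if its parent was expanded, so the cut is well defined even when
noisy, partially inconsistent intervals are supplied.

Two deliberate simplifications, both stated rather than hidden:

* only CIs enter the verdict; point estimates are ignored. Intervals are
  treated as opaque (no HPD versus equal-tailed distinction).
* verdicts are per-comparison; the 95% level is not propagated into a joint
  probability over whole complements.

For the worked opsin example, note one wrinkle: the oldest duplication
interval (615--587 Ma) *overlaps* the divergence interval of the oldest focal
lineage (595--572 Ma), so the strict rule returns `ambiguous` there -- and the
conservative resolution still yields the published single-gene complement.
The audit trail written by `run_infer()` records every such verdict.

## Naming and the duplication-chain object

Ancestral genes are named by slash-concatenating their terminal descendant
paralogues in a fixed precedence order (`Rh7, UV, SWS, MWS, LWS` by default),
e.g. `MWS/LWS` for the ancestor of the two long-wave opsins. Because
published spellings vary in component order, `same_gene()` compares names on
their component *sets*. `gene_lineage_tree()` assembles the dated duplication
chain from an event table (one row per duplication: the two daughter leaf
sets plus a CI), validates that the partitions nest and that a daughter
duplication is never entirely older than its parent, and is invariant to the
input order of events.

## Reconciliation

Where the gene history is given as a gene tree rather than a dated chain,
`lca_reconcile()` maps it onto the species tree by standard LCA (parsimony)
reconciliation: each gene node maps to the lowest species node containing its
descendant species, and a node is a duplication iff it maps to the same
species node as one of its children. This attains the parsimony minimum
number of duplications (verified against an exhaustive brute-force
enumeration in the test suite). Probabilistic, gene-tree-aware
reconciliation is deliberately out of scope: downstream inference only uses
the *placement* of duplications on a fixed species topology. Losses are not
reconstructed as events; `copies_at()` counts gene lineages with surviving
descendants, so secondary loss shows up as reduced tip counts. Multifurcating
nodes are handled by the same LCA semantics without binarization, which
treats polytomies as soft.

`copies_at()` answers "how many gene lineages were inherited at the base of
this species node": a lineage counts when its birth event maps strictly above
the node (or is a duplication that LCA mapping has pulled down onto the node
itself, which is where stem-lineage duplications land when only extant
genomes are sampled), when it did not itself end above the node, and when it
has at least one surviving descendant copy below. For a congruent single-copy
family this gives 1 everywhere.

## Phylogenetic bracketing

For internal nodes all of whose sampled descendants are extant,
`bracket_extant()` uses Dollo logic on a presence/absence table: a gene is
attributed to the node iff the node lies at or below the MRCA of the species
possessing it (and at least one descendant possesses it). Presence in two or
more child subtrees therefore forces presence at the node, while a gene found
in a single tip is never projected onto that tip's ancestors. Nodes with
fossil descendants are refused with a pointer to `infer_complement()`, since
fossils cannot contribute presence data.

## Chromacy

`chromacy()` maps a complement to a colour-vision class by counting
spectrally usable genes: 1 = monochromat, 2 = dichromat, 3 = trichromat,
more = polychromat. A standalone `Rh7` is discounted as non-visual by default
(its characterized role is circadian entrainment), but composite ancestors
containing Rh7 as a component still count; the discount is switchable
(`rh7_nonvisual = FALSE`).

## The synthetic-data generator

Real inputs to this kind of analysis are posterior summaries from MCMC
dating software. The generator emulates those outputs so the whole pipeline
is testable end to end:

* **Species trees** (`simulate_species_tree()`): forward birth--death
  simulation from a root age drawn from a Gamma prior with mean 600 Ma and
  sd 26 Ma (the calibration scale of the Ediacaran origin of Ecdysozoa),
  conditioned on both root children surviving to be sampled. Extant tips are
  retained with probability `rho`; fossilization events occur along branches
  as a Poisson process with rate `psi` per lineage per Ma and become dated
  fossil tips. `rho` and `psi` are used as direct generator parameters, not
  priors: the generator's job is to emulate plausible fossilized birth--death
  *output*, not to re-implement the FBD likelihood. The empirical analysis
  this emulates used `rho = 1e-5` against the ~10^7 extant arthropod species;
  at the tens-of-tips scale of a forward simulation that literal value would
  leave nothing sampled, so the defaults (`birth = 0.012`, `death = 0.006`,
  `rho = 0.25`, `psi = 0.004`) were chosen once to produce trees of the same
  shape as the empirical one -- tens of sampled extant tips and a modest
  number of fossil tips -- and are not tuned thereafter.
* **Duplication histories** (`simulate_duplications()`): a chain of events on
  a backbone root-to-tip path, at explicit times or at Poisson-process times;
  the default scenario uses 4 backbone duplications and 5 focal divergences,
  mirroring the structure of the opsin example.
* **Posterior emulation** (`simulate_age_posteriors()`): for a true age $t$,
  a posterior location is drawn as $\log m \sim N(\log t, \sigma^2)$ and
  `n_samples` draws are taken around $m$ with the same log-scale spread
  $\sigma$; the emitted CI is the equal-tailed interval of the draws. Matching
  the two spreads makes the nominal level the asymptotic coverage of the
  truth -- a single-level scheme centred on the truth would cover ~100% of the
  time. The default `rel_sd = 0.01` yields interval widths around 20--25 Ma
  at 600 Ma, comparable to the printed intervals of the worked example (a
  modeling choice, as the empirical widths are known only for a few nodes).
  `rel_sd = 0` gives degenerate intervals for exact-recovery tests. Where
  noise locally inverts parent/child order, a postorder max-propagation
  restores age monotonicity; on well-separated nodes this clip almost never
  binds.

`evaluate_recovery()` scores inferred complements against the truth:
*overclaim* (a paralogue included although its true duplication postdated the
true divergence), *underclaim* (ancestral gene conservatively kept although
the duplication truly preceded), *exact*. The one-sided construction of the
rule predicts an overclaim rate of at most ~2.5% per comparison with
calibrated 95% intervals; the acceptance suite tests the looser 5% bound.
Underclaim is the price of conservatism and grows with interval width, which
is also tested (three width levels, monotone).

## Problem sizes and numerical choices

The replicated experiments use `birth = 0.008`, `death = 0.004` (expected
~20 sampled tips per replicate), 300 posterior draws per node, 1000
replicates for the overclaim bound, 100 for zero-noise exactness, and 200 per
width level for the underclaim trend; the brute-force reconciliation oracle
corpus is 500 random gene/species tree pairs with at most 7 gene tips. These
sizes give stable rates while keeping a full run in minutes on one CPU.
Age comparisons use strict inequalities at interval boundaries; validation
tolerances are 1e-6 Ma. Ties in tree traversal order are fixed by node index,
and all generators are deterministic given a seed.

## Known limitations

* The LCA stand-in places stem-lineage duplications at the crown node below
  them; `copies_at()` compensates when counting inherited lineages, but the
  *branch*-level position of a duplication within a stem is not resolved.
* No complement posterior: ambiguity is collapsed conservatively instead of
  being propagated as probability.
* The generator emulates summary-level dating output, not the autocorrelated
  clock process itself; passing tests show the inference machinery is
  correct and conservative under calibrated intervals, not that any
  particular empirical dataset's intervals are well calibrated.
* Lineage-specific gains and losses after a stem divergence are outside the
  model, exactly as they are caveated in the underlying inference logic.

## A worked run

```{r worked}
fx <- ecdysozoan_opsins()
fx$gene_tree
tab <- infer_all(NULL, fx$gene_tree, fx$divergences)
tab[, c("lineage", "div_young", "div_old", "complement", "size", "chromacy")]
glance(tab)
```

```{r plot, fig.width = 7, fig.height = 4}
autoplot(fx$gene_tree, divergences = fx$divergences)
```
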