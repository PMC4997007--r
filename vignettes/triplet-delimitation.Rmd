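---
title: "Delimiting species from rooted triplet distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting species from rooted triplet distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplimit)
```

## The model

`triplimit` delimits species from a collection of rooted gene trees, one per
locus, under the multispecies coalescent (MSC). Its unit of evidence is the
*rooted triplet*: for any three samples $(a, b, c)$ each gene tree displays
one of three topologies, $ab|c$, $ac|b$, or $bc|a$. Counting topologies
across $N$ independent loci gives counts $X = (n_1, n_2, n_3)$, and the MSC
fixes their distribution in the two situations the method must tell apart:

* **One panmictic species (W).** Any pair of lineages is equally likely to
  coalesce first, so $X$ is an equiprobable trinomial,
  $P_W(X) = \binom{N}{n_1\,n_2\,n_3} (1/3)^N$.
* **Two or three species (B).** The topology concordant with the species
  tree (the *dominant* topology $\nu$) occurs with probability
  $1 - \tfrac{2}{3} e^{-\lambda}$, each discordant topology with probability
  $\tfrac{1}{3} e^{-\lambda}$, where $\lambda$ is the length of the relevant
  internal species-tree branch in coalescent units (generations divided by
  the effective population size $N_e$). $X$ is then a skewed trinomial.

The observer knows neither the species tree underlying a triple nor
$\lambda$. Each triple therefore gets six equally weighted candidate models:
three "B" models (one per candidate dominant topology) and three matching
"W" models, with a uniform prior $\lambda \sim U(0, L)$. Conditioning
instead on the *observed* majority topology would bias the comparison toward
splitting; summing over all three candidates is the correction. The
per-model marginal likelihood has a closed form: for a "W" model it is
$L \cdot P_W(X)$, and for a "B" model the substitution
$x = \tfrac{2}{3}e^{-\lambda}$ turns the integral into a difference of
incomplete beta functions,

$$\int_0^L P_B(X \mid \lambda, \nu)\,d\lambda =
  \left(\tfrac12\right)^{a} C \left\{ \beta(\tfrac23;\, a,\, n_\nu + 1) -
  \beta(\tfrac23 e^{-L};\, a,\, n_\nu + 1) \right\},$$

with $a = N - n_\nu$ the minority total and $C$ the multinomial
coefficient. `triplet_posterior()` turns these into $P(W \mid X)$ and
$P(B \mid X) = 1 - P(W \mid X)$.

A *delimitation* assigns every sample to a species. Its score adds
$\log P(W \mid X)$ over triples whose members share a species and
$\log P(B \mid X)$ over the rest. Because triples overlap, the score is a
composite objective rather than a true posterior probability of the
delimitation; it is the quantity the search maximizes.

```{r posterior-example}
# 20 of 25 loci agree on one topology: almost certainly between species
exp(triplet_posterior(c(20, 3, 2))$log_post_B)
# near-uniform counts: almost certainly one species
exp(triplet_posterior(c(9, 8, 8))$log_post_W)
```

## The search

Candidate delimitations are constrained by a rooted binary *guide tree* over
the samples: a species is any subtree, and a delimitation is a set of
disjoint subtrees covering all tips. A guide with $S$ tips carries between
$S$ and roughly $\lfloor 1.5^S \rfloor$ such delimitations, too many to
enumerate at scale, but the additivity of the score over triples gives the
problem optimal substructure: every triple is interior to exactly one
guide node (the MRCA of its three tips), so the best delimitation of a
subtree combines the best delimitations of its children plus a constant for
the crossing triples. `best_delimitation()` exploits this in a single
postorder pass — two score evaluations per node — and is exactly optimal
(`enumerate_delimitations()` provides the brute-force check used in the
tests). At exact score ties the search prefers lumping: a pair of species
contributing fewer than two samples each to every triple is indistinguishable
from one species under this model, and resolving such ties toward fewer
species makes the method conservative against over-splitting.

When no guide tree is supplied, `build_guide_tree()` assembles one from the
count table itself by the Aho BUILD recursion on each triple's modal
topology, weighted by its margin (modal count minus runner-up). Incompatible
constraint sets lose their lowest-margin triplets until the recursion can
proceed; regions without signal become polytomies resolved uniformly at
random under the caller's seed. This majority-triplet consensus is
deliberately simple plumbing: delimitation accuracy tolerates guide noise,
and the downstream effect of a mis-placed sample is an over-split, not a
wrong merge.

## Tunable parameters

* `L` (coalescent units; default 5): upper bound of the uniform prior on
  $\lambda$. It spans dominant-topology frequencies from $1/3$ ($\lambda =
  0$) to $1 - \tfrac23 e^{-5} \approx 0.996$, which covers realistic
  divergences; raising it dilutes the "B" marginal for weakly skewed counts
  and so makes splitting slightly harder. Changing `L` changes results and
  is recorded in output headers.
* `quadrature_tol` (default `1e-9`): relative tolerance of the adaptive
  quadrature used only in the zero-minority-count branch ($a = 0$), where
  the incomplete beta is undefined and the integrand
  $(1-x)^{n_\nu} x^{-1}$ is integrated directly on the strictly positive
  interval $[\tfrac23 e^{-L}, \tfrac23]$. The result there depends only on
  $N$, so it is cached per table.
* `unresolved` policy in `count_triplets()` (default `"skip"`): a locus in
  which a triple is a polytomy contributes nothing. The alternative the
  empirical workflow uses is to resolve whole gene trees randomly per
  replicate (`resolve_polytomies()`), which preserves the within-locus
  correlation among triples; the per-triple `"random"` policy exists for
  completeness but breaks that correlation.
* `min_margin` in `build_guide_tree()` (default 0): modal triplets whose
  margin does not exceed it are treated as unresolved. The default uses
  every uniquely modal triple.

Numerical policy throughout: all probability arithmetic is in natural-log
space with log-sum-exp reductions (multinomial coefficients via
`lgamma`, incomplete betas via `pbeta(log.p = TRUE) + lbeta` with a
`log1p`-based difference), so counts of hundreds of loci per triple are
safe. Branch lengths are parsed and preserved but ignored by the model,
which uses topology only; rooting is taken as given.

## The simulator

`simulate_gene_trees()` implements the standard MSC: within a species-tree
branch with population size $N_e$, each pair of lineages coalesces at rate
$1/N_e$ per generation (a haploid-style rate; `ploidy` rescales it);
looking backward, the surviving lineages of the two daughter populations
merge at each speciation node; coalescence finishes in the ancestral
population above the root. Branch lengths are in generations, so the
coalescent-unit length of a branch — the $\lambda$ of the model above — is
its duration divided by $N_e$. The tests verify this calibration directly:
the frequency of species-tree-concordant triplets tracks
$1 - \tfrac23 e^{-\lambda}$ across $\lambda \in [0.25, 4]$ at binomial
resolution, pairwise coalescence times average $N_e$ generations, and a
single population yields the three topologies in equal proportion.

Two study designs are built in. `three_species_tree()` is the fixed
asymmetric tree $((sp_1, sp_2), sp_3)$ with divergences at 4,000 and 8,000
generations. `simulate_yule_species_tree()` draws a pure-birth tree
conditioned on its tip count and rescales it to a fixed root depth (20,000
generations by default), so the speciation rate drops out. The sampling
time is drawn by the general sampling approach for conditioned birth
processes: a uniform point within the era during which exactly $n$ lineages
exist. This choice matters — it sets the distribution of the youngest node
ages relative to the depth, and with it the intensity of incomplete lineage
sorting. Under it, the 10-species design with 40 loci and 10 samples per
species shows a mean proportion of nonmonophyletic species of about 0.32 at
$N_e = 1250$ and about 0.97 at $N_e = 20{,}000$ (50 replicates;
`scripts/acceptance.R` recomputes both).

What the simulator does *not* emulate: gene-tree estimation error (inputs
are true genealogies), gene flow and hybridization, intra-locus
recombination, and linked loci. Passing simulation tests therefore
demonstrates correctness of the method under its own model assumptions, not
robustness to their violation in real data.

## Design choices in the studies

`run_three_species_study()` scores four fixed hypotheses per replicate —
all-one-species, the true three species, the sister pair lumped, and one
species bipartitioned into two random halves (the over-split) — and reports
the rate of choosing the over-split (false positive) and of failing to beat
the true partition with a lumped one (false negative). The bipartitioned
species is the grouping detail the over-split hypothesis needs but the
design leaves open; under panmixia every fixed bipartition is statistically
equivalent, so a seeded random split of one species' samples is used.

`run_ten_species_study()` measures recovery of Yule-simulated species
either with the true species tree as guide (`known_guide`; each species'
samples attached as a seeded random subtree, whose shape is irrelevant
whenever the species is lumped) or with a guide estimated from the gene
trees themselves (`estimated_guide`). Replicate seeds are derived so that
enlarging the replicate count extends, rather than reshuffles, the earlier
replicates.

Problem sizes in the packaged tests and in `scripts/acceptance.R` follow
the study designs at 20–50 replicates per condition, which resolves the
reported rates at the precision their comparisons need.

## Known limitations

* A pair of species each contributing fewer than two samples to every
  triple cannot be separated (the skewed trinomial does not distinguish the
  two-species from the three-species arrangement of a triple), and a
  species pair whose divergence is a small fraction of $N_e$ generations is
  unsplittable in principle: the crossing triples' dominant-topology
  probability is then indistinguishable from $1/3$. Empirically, with 25
  loci and 10 samples per species the dynamic program starts splitting
  pairs at divergences of roughly $0.4\,N_e$ generations and is reliable
  from about $N_e$ generations. In the Yule design this makes recovery of
  *all* species depend on the age of the youngest speciation, a property of
  the species tree rather than of the data volume.
* The score treats overlapping triples as independent, so it is not a
  calibrated posterior; absolute score differences between delimitations
  should be read comparatively (per-node margins are exposed in
  `best_delimitation()$node_margin` and in the verbose CLI output).
* The search never rearranges the guide tree; samples misplaced in the
  guide surface as over-splits, and the co-assignment matrix of
  `cmd_delimit(replicates > 1)` is the intended tool for spotting them.
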