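---
title: "Methods: top-down tumor phylogeny inference from mutation presence/absence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: top-down tumor phylogeny inference from mutation presence/absence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pti)
```

## The model and its assumptions

`pti` reconstructs a rooted phylogeny whose leaves are tumor biopsies of one
patient, using only which somatic mutations are present in which sample.
The underlying model is clonal evolution with gradual mutation
accumulation: each mutation arises once on some lineage and is inherited by
all descendant clones, so the set of samples carrying a mutation should be
a clade of the sample tree, and the number of mutations shared exclusively
along a lineage measures the length of the corresponding branch. Two
assumptions matter in practice:

* **One major clone per biopsy.** Each sample is treated as a single point
  on the tree. Biopsies containing two sizeable subclones violate this; the
  behavior in that case is characterized below.
* **No back-mutation / loss.** A called mutation is assumed not to revert.
  Deletions and calling errors both surface as noise and are tolerated, not
  modeled.

Because only presence/absence enters the computation, the method is
insensitive to the allele-frequency inaccuracies of shallow or FFPE-derived
sequencing and applies unchanged to any binary feature-by-sample matrix.

## The split statistic

After removing the root trunk (mutations present in all samples), the
sample set is split top-down. At a node with $n$ samples all split shapes
$(t, n-t)$, $t = 1..\lfloor n/2\rfloor$, and all $\binom{n}{t}$
combinations per shape are enumerated. For each combination $c$ of size
$t$, $\theta_{tc}$ counts the mutations carried by **every** member of the
larger group; when $n$ is even and $t = n/2$ there is no larger group and
$\theta$ is the smaller of the two halves' counts, with unordered
bipartitions enumerated once each. The split size is scored by

$$\partial_t = \frac{\theta_{t\,max}}{\theta_{t\,sec\_max}},$$

the ratio of its best to second-best combination. If the node's true first
split has shape $(t_0, n-t_0)$, then at $t = t_0$ exactly one combination
(the true one) has support, while at larger $t$ several subsets of the true
clades are supported and at smaller $t$ none are — so $\partial$ is
maximized, typically uniquely, at the true shape. On perfect-phylogeny
input this argument is exact and recovery is guaranteed, which the
acceptance suite confirms over 200 random scenarios.

Two degenerate cases need a total order:

* $\theta_{sec\_max} = 0 < \theta_{max}$: the winner is unopposed,
  $\partial = \infty$.
* $\theta_{max} = 0$: the shape carries no signal, $\partial = 0$. If this
  happens for every shape at a node, no binary split has any support and
  the node is emitted directly as a multifurcation over its samples rather
  than inventing an arbitrary split.

$\theta$ deliberately requires no absence outside the group (plain
intersection). Fully shared rows are already removed with the trunk at each
level, and requiring exclusivity would make the statistic brittle under
false-positive calls.

## Ties, tree weight, multifurcations

Distinct bipartitions can tie on $(\partial, \theta)$ — within one shape or
across shapes. Every tied choice is pursued, and each complete tree $T$ is
scored by the aggregated mutation count

$$W_T = \sum_{i=1}^{k}\sum_{j=1}^{N_i} \omega_{ij}\,\chi_{ij},$$

summing branch length $\omega$ (mutations on the branch) times subtended
leaf count $\chi$ over all internal non-root branches; the root trunk
(level $i=0$) is common to all candidates and excluded, as are leaf
branches. The largest $W_T$ wins; exact $W_T$ ties are reported as multiple
solutions, ordered deterministically by the canonical serialization
(children sorted by smallest descendant leaf), so identical inputs always
produce byte-identical outputs. Tie cascades are capped at `max_trees =
100` candidates with a warning; no study condition in the test suite comes
near the cap.

Internal branches that end up with no assigned mutation are collapsed into
their parent, which is how more-than-two-way splits are recovered from a
binary recursion.

## Mutation assignment and accounting

The recursion chooses the topology; mutations are then placed by a global
rule: each mutation goes to the highest node whose subtended leaf set is
contained in the mutation's carrier set. When that maximal node is not
unique — possible only for carrier patterns inconsistent with the topology,
e.g. noise-induced patterns straddling two clades — the mutation is placed
on no branch and reported in `unassigned`. A naive "assign during
recursion" rule would place such a row once in each subtree it touches,
breaking the one-branch-per-mutation invariant; the global rule keeps the
accounting identity

$$\sum \text{branch lengths} + |\text{unassigned}| + \text{dropped all-zero rows} = m$$

exact on every input (asserted throughout the test suite), and coincides
with the recursion's bookkeeping whenever the input is a perfect phylogeny.

## Parameters

* `vaf_threshold` (default **0.01**): presence calling, $M_{ij}=1$ iff
  $\mathrm{VAF}_{ij} \ge$ threshold; equality counts as present. This is the
  method's single scientific parameter. The default assumes the input is
  already a confidently called somatic mutation set; raise it (e.g. 0.03)
  for noisy call sets.
* `af_filter` (default off, conventional value **0.1**): optional
  pre-filter keeping mutations whose *maximum* VAF across samples passes
  the cutoff. The per-mutation maximum (rather than per-sample filtering)
  keeps the binary pattern of a retained mutation intact. Intended for
  hypermutated patients where the matrix would otherwise be huge.
* Missing VAFs (sample not covered at a site) are treated as absent; the
  matrix is strictly binary with no missing state.
* Nodes with more than 25 samples are rejected ($\binom{n}{\lfloor n/2
  \rfloor}$ explodes); multi-region studies are typically $n \le 10$.

## The simulator

`sim_scenario()` / `realize_matrix()` generate the study conditions for all
property tests: a uniform random rooted binary labeled topology (sequential
uniform edge insertion, verified uniform by chi-square over all 15 shapes
at $n=4$), $1 + \mathrm{Poisson}(\text{branch\_rate}-1)$ mutations per
branch (the +1 floor guarantees noise-free scenarios are exact perfect
phylogenies; deliberately empty branches are tested by explicit
construction instead), independent bit flips at `fn_rate` / `fp_rate`, and
an optional two-subclone biopsy: the mixed sample retains each
own-lineage-specific mutation with probability $1-f$ and gains each
mutation founding the designated second clade with probability $f$ — a
binary-thresholding caricature of a two-clone mixture.

What the simulator does *not* emulate: read-level sampling noise tied to
coverage, copy-number loss of heterozygosity, purity variation between
biopsies, or correlated (regional) miscalls. Passing tests therefore show
correctness of the algorithm under its own model, not robustness to every
real-data artifact.

With a mixed sample, the inferred placement follows the clade contributing
more mutations to the biopsy. Because $W_T$ weights the deep branch of the
three-sample grouping by $\chi=3$ against $\chi=2$ for the cherry, the
exact flip occurs at $3k_{second} = 2k_{own}$ rather than at equal counts;
empirically placement is 100% with the own clade at $f \le 0.2$ and 100%
with the second clade at $f \ge 0.8$ (50 seeds per setting), with the
crossover near $f = 0.45$.

## Numerical and design choices

* $\partial$ lives on $[0,\infty]$; comparisons use IEEE `Inf`, no epsilon
  is needed since $\theta$ are integers and ratios of integers are exact in
  double precision at these magnitudes.
* Problem sizes in tests: recovery over 200 scenarios at $n \in [3,10]$,
  branch rates 5 and 20; oracle equivalence over 1,000 random 6-sample
  matrices against a brute-force per-sample set-intersection and a per-row
  scan; 50 Monte-Carlo seeds per mixing fraction. The full suite runs in
  well under a minute.
* The similarity score compares, per leaf, the ordered sequence of clades
  on its root-to-leaf path after collapsing zero-length internal branches
  in both trees, and averages the per-leaf indicator. This per-leaf
  decomposition yields the fractional scores needed for benchmarking; it is
  this package's reconstruction of the metric (the original supplementary
  definition is not public), so scores computed here should be compared
  against published values only qualitatively.
* Inference is fully deterministic: no randomness anywhere outside the
  simulator, and candidate ordering is canonical.

## Known limitations

* Exclusivity-free $\theta$ means heavy false-positive noise can inflate
  support for wrong groupings; the AF pre-filter is the mitigation.
* Tied multiple solutions are enumerated, not probabilistically weighted;
  there are no branch confidence values.
* Subclonal decomposition within a biopsy, VAF clustering and cellular
  prevalence estimation are out of scope by design.
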