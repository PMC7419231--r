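---
title: "Ancestral genome reconstruction from signed synteny blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral genome reconstruction from signed synteny blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjmedian)
```

## The problem

Closely related plant genomes — the diploid *Brassica* species are the
motivating case — differ by large-scale rearrangements: inversions,
translocations, chromosome fusions, fissions and transpositions.  Once each
genome is reduced to an ordered list of signed, shared synteny blocks, these
differences become arithmetic: the double-cut-and-join (DCJ) model counts
the minimum number of cut-and-rejoin operations separating two block orders,
and an ancestral genome can be sought as the *median* — the block
arrangement minimising the summed DCJ distance to the extant genomes.
`dcjmedian` implements that whole chain — block construction from an
orthologue table, distances, the median, ancestral "painting", ultrametric
root placement, and divergence dating from synonymous substitution (Ks)
distributions — together with a simulator that makes every stage testable
against known truth.

## The DCJ distance

A marker (block) $m$ has two extremities, tail and head.  A genome is
exactly a set of *adjacencies* (unordered pairs of neighbouring extremities)
and *telomeres* (chromosome-end extremities).  For two genomes $A$ and $B$
on the same $N$ markers, the adjacency ("breakpoint") graph joins their
elements through shared extremities and decomposes into cycles and paths;
with $C$ cycles and $I$ odd-length paths,

$$ d_{\mathrm{DCJ}}(A, B) = N - \left(C + \frac{I}{2}\right). $$

A path's parity is its number of edges, which equals the number of
extremities in the component; this convention makes $I$ even and $d$ an
integer, and it is pinned down in the test suite by an independent oracle:
breadth-first search over all single-DCJ moves must give the same value on
random small genomes.  One DCJ step covers inversions, translocations,
fusions and fissions; a transposition requires two (a circular excision and
its reintegration), which is how the simulator counts it.

`sorting_scenario()` extracts one optimal operation series by realising
every target adjacency in lexicographic order and then cutting surplus
adjacencies; each step reduces the distance by exactly one, so the series
length equals the distance and replay is a strong self-check.

## The median and its bounds

For three genomes with pairwise distances $d_{1,2}, d_{2,3}, d_{1,3}$ the
total distance $d^{\Sigma}$ of any median obeys

$$ \left\lceil \tfrac{d_{1,2}+d_{2,3}+d_{1,3}}{2} \right\rceil \;\le\;
   d^{\Sigma} \;\le\; d_{1,2}+d_{2,3}+d_{1,3} - \max(d_{1,2},d_{2,3},d_{1,3}), $$

the upper bound being attained by placing the median on the input genome
closest to the other two.  `median_bounds(96, 98, 52)` — the distances
published for the *B. rapa* / *B. nigra* / *B. oleracea* trio — gives
(123, 148).

The median problem is NP-hard, so `solve_median()` offers two modes.

**Exact** is a branch-and-bound over median adjacency choices on the
multiple breakpoint graph.  Adjacencies (and telomeres) present in all three
genomes are fixed first — such unanimous elements belong to some optimal
median, the simplest of the "adequate subgraph" reductions — and the
remaining extremities are branched in order of leaf support.  Partial
assignments are pruned with a completed-component bound: components already
closed contribute their cycles and odd paths, and each undecided extremity
can contribute at most half a cycle per leaf.  The search is certified
(`optimal = TRUE`) when it exhausts the space or attains the lower bound;
a node budget (default $10^6$) turns it into a best-found search on large
instances, reported as such rather than silently.  On marker universes of
up to four markers the exact mode is verified against exhaustive
enumeration of *every* genome (all extremity matchings, circular
chromosomes included).

**Heuristic** is a steepest-descent local search over the single-DCJ moves
that realise an adjacency or telomere of some input genome, started from
each input genome and from a majority-vote consensus.  Moves are ranked
lexicographically by (total distance, then total adjacency agreement with
the three inputs); equal-distance moves are accepted only when agreement
strictly increases, so the search terminates.  The agreement tie-break
matters: medians are rarely unique, and among equally parsimonious
solutions the one sharing most adjacencies with the inputs is the natural
point estimate of the ancestor.  Because the three input genomes are
starting points, the heuristic can never exceed the upper bound; when it
reaches the lower bound the result is optimal and flagged so.

At the simulator's default study scale (50 blocks, 8 chromosomes, branch
budgets 5/5/15) the heuristic lands on the certified optimum or within one
operation of the lower bound in almost all seeded trials.  Note that the
exact ancestor is not always recoverable even in principle: with 25 events
on 50 blocks some optimal medians sit two or three operations away from the
true ancestor, a genuine identifiability limit rather than a search
failure.

## Blocks from an orthologue table

`build_blocks()` starts from a three-genome syntelog table (family,
genome, chromosome, coordinates, strand).  Families without exactly one
copy per genome are dropped and counted — unresolved post-polyploidy
paralogues cannot anchor a 1:1:1 block.  The first label alphabetically
serves as reference; the table is chained reference-vs-each-other-genome by
sparse dynamic programming over anchors (per chromosome pair, both
orientations, score = anchors − 0.05 per skipped gene, greedy best-chain
extraction), and blocks are maximal reference-consecutive runs lying in one
chain of *both* partitions — i.e. collinear in all three genomes.  Block
orientation per genome is the majority strand agreement with the reference.

The one tunable that matters is `max_gap_genes`.  Brassiceae genomes carry
a whole-genome triplication whose subgenomes retain roughly 70%, 49% and
42% of their genes; after such fractionation, two neighbouring anchors
shared by a genome pair are separated by a geometric number of
retained-but-unshared genes.  At the rates above the pairwise-shared anchor
density is ~0.34–0.49 per gene, so a 5-gene cap would split of order a
quarter of all blocks, while 10 covers beyond the 99.9th percentile of
gaps; the default is therefore 10 (with `min_anchors = 3`).  These
thresholds are package choices — chaining cutoffs of this kind are rarely
printed in papers — and both are explicit `chain_params()`.

`blocks_to_genomes()` turns the block set into signed block-order genomes
(sign = orientation relative to the reference), and `paint_ancestral()`
labels every extant placement with the median chromosome carrying its
block, the table behind ancestral-karyotype painting figures.

## Divergence dating

Ks values for syntelog pairs are filtered (`Ks > 0.001`, removals
counted), log-transformed, and fitted with Gaussian mixtures for
$k = 1..k_{\max}$ components by EM.  Initialisation uses quantile-spaced
means, the pooled standard deviation and uniform weights; ten seed-jittered
restarts are run for 40 iterations each and the best is polished to a
relative log-likelihood tolerance of $10^{-8}$ (at most 1,000 iterations);
$k = 1$ has a closed-form MLE.  The log-likelihood trace is checked for
monotonicity on every fit.  Model choice minimises

$$ \mathrm{BIC}(k) = (3k - 1)\,\ln n - 2\,\ell_k, $$

with $3k-1$ free parameters ($k$ means, $k$ standard deviations, $k-1$
weights); the full BIC trace is kept.  `chi2_goodness()` bins the data,
merges bins with expected counts below five, and tests observed against
model-expected counts on $\mathrm{bins} - 1 - (3k-1)$ degrees of freedom —
approximate, since the parameters were fitted unbinned, but calibration
simulations in the test suite show near-nominal rejection rates.

`peak_to_time()` converts a component mean $\mu$ on the ln(Ks) scale to a
divergence time $T = e^{\mu} / (2r)$ under a synonymous clock of rate $r$
substitutions/site/year.  There is deliberately no default $r$: plant
lineages differ several-fold, so the rate must be supplied.

`place_ancestor()` takes the three median-to-leaf distances, treats the
two ingroup branches as equal in expectation (their mean is used; the
asymmetry of the actual pair is retained in the report), and roots the
tree on the median-to-outgroup edge at the offset $x$ solving
$d_{\mathrm{out}} - x = x + \bar d_{\mathrm{in}}$, which equalises
root-to-leaf depths.  For per-leaf distances (26, 28, 70) with the 70-leaf
as outgroup this puts the root 21.5 operations from the median — about 31%
of the way along that edge.  If the distances are grossly non-clock-like
the offset is clamped into $[0, d_{\mathrm{out}}]$ with a warning rather
than extrapolated.

## The simulator: what it emulates, and what it does not

`simulate_triple()` draws a random ancestor (default 50 signed blocks on 8
linear chromosomes), then evolves three descendants independently with
5/5/15 rearrangement events — two close genomes and one
rearrangement-rich lineage, the topology of the *Brassica* A/C versus B
split.  Events are sampled as reversal 0.6, translocation 0.2, fusion
0.05, fission 0.05, transposition 0.1: intrachromosomal inversions
dominate plant comparative maps, and the rest are kept rare but present.
Reversal spans are uniform over intervals of a chromosome; translocation
and fission breakpoints are uniform; every event's adjacency-level DCJ
operations are logged so histories replay exactly.

`simulate_syntelog_table()` expands each block into gene families (default
60 per block — scaled down from the ~145 implied by 25,866 orthologues in
178 blocks, but dense enough that three-way shared anchors survive
fractionation) and retains families per genome with probability 0.70, 0.49
and 0.42, the subgenome retention rates reported for Brassiceae; at least
two families per block are forced so a block is never silently
unrecoverable, and the forcing count is recorded.  Coordinates sit on a
fixed 1 kb/0.5 kb grid.

Two sampling facts discovered while validating deserve a note.  First,
rearrangement events stop being additive well before the naive limit: at
$k$ events on $n$ blocks the probability that the DCJ distance equals $k$
decays roughly with $k^2/n^2$, and at $k = n/4$ it is only ~75% — the test
suite therefore asserts exact additivity in the $k \le n/8$ regime and only
the $d \le k$ bound beyond.  Second, with 25 events on 50 blocks the median
and the ancestor separate occasionally (see above), which bounds how sharp
any ancestor-recovery check can be.

What the simulator does **not** emulate: gene-level sequence evolution,
tandem duplication, segmental duplication beyond the retention model,
missing or mis-assembled regions, and biased fractionation along
chromosomes.  Passing the recovery tests therefore demonstrates the
correctness of the inference machinery under the stated rearrangement
model, not robustness to every artefact of real assemblies.

## Numerical and design choices

* Marker ids need not be contiguous; the shared universe is computed and
  content mismatches are an error at the genome layer (silent dropping is
  reserved for the block builder, where it is counted).
* Genome equality is defined on adjacency/telomere sets, so chromosome
  order, names and whole-chromosome flips are representation, not signal.
* Circular chromosomes are supported as inputs and can appear in medians;
  the median result reports them rather than forbidding them.
* Scenario extraction and the exact search break ties lexicographically on
  extremity codes, so all outputs are deterministic; the heuristic uses no
  randomness at all, and every simulator draw derives from one integer
  seed.
* Problem sizes in the test suite (50-block medians, 40-block recovery
  tables, 5,000-point mixtures, 100-seed sweeps) were chosen as the
  smallest scales at which the statistical claims are meaningful.

## Limitations

* The exact median search certifies optimality only within its node
  budget; 178-block instances generally finish via the heuristic plus
  bound attainment, not exhaustion.
* Only three-genome medians are implemented — no $k>3$ medians and no
  small-parsimony labelling of larger trees.
* The DCJ model here assumes equal marker content (no indel/duplication
  DCJ variants); content differences must be resolved upstream by the
  block builder.
* Ks values are consumed, not computed: alignment and substitution-model
  estimation live outside this package.
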