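---
title: "Methods: gene-family dynamics by Dollo parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family dynamics by Dollo parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dollodyn)
```

This vignette is the package's account of its methods: the models and
rules it implements, the assumptions behind them, the parameters that
matter, and the choices made where the design was genuinely open. The
numbers shown are computed by the code in this document; everything else
the package claims is established by the test suite and
`scripts/acceptance.R`, not asserted here.

## The inference problem

Given a rooted species tree and, per protein-coding gene family, which
species carry how many copies, we ask where on the tree each family was
gained, duplicated and lost, and what the ancestral proteomes looked
like. Upstream of that question sits the construction of the families
themselves from an all-vs-all protein similarity network; downstream sit
repertoire analyses: which families are anciently conserved, which are
clade novelties, which encode transcription factors, transporters or
secreted proteins, and how gene content diverges across species.

## Homologous-group construction

The similarity network is consumed as a tabular edge list (`protein1`,
`protein2`, `score`, `evalue`, `cov_long`, `cov_short`) — the dialect of
all-vs-all search tools. Three stages follow.

**Hit filtering** (`filter_hits()`): asymmetric coverage ≥ 0.2 of the
longer and ≥ 0.8 of the shorter protein, e-value ≤ 1e-4. The asymmetry
admits matches of a domain against a multidomain protein while rejecting
spurious short local hits.

**Markov clustering** (`mcl_cluster()`, inflation 2.0): expansion (matrix
squaring) alternating with inflation (entrywise power, column
renormalization) on the column-stochastic transition matrix. Numerical
choices, all standard MCL practice and needed for convergence: self-loops
set to each node's maximum incident weight; entries below 1e-8 pruned
after each inflation; convergence declared when the matrix changes by
less than 1e-6, with a cap of 100 iterations (a warning is issued and the
current matrix interpreted if the cap is hit). Clusters are read off as
connected components of the limit support, which makes the result
invariant to node relabelling; cluster ids are assigned by each cluster's
lexicographically smallest member so runs are comparable.

**Cluster network, pruning, merging.** Clusters are linked by the number
of inter-cluster protein edges, normalized to cluster size. The source
method does not say *which* size; we divide by the smaller of the two, so
a small cluster strongly attached to a large one ranks as a strong link
(`normalize = "mean"` is available). The network is then reduced until
every component has unweighted diameter ≤ 3. The reduction is described
in the source as excluding the weakest *nodes* while sorting
*connections*; pruning edges is the only reading under which a diameter
criterion over clusters stays meaningful, so we remove, per offending
component, the minimum-weight edge (ties broken by lexicographic id
pair) and iterate — which terminates in at most |E| rounds. Finally,
cluster pairs still linked are merged when a profile comparison meets all
four criteria: e-value ≤ 1e-10, profile-side coverage ≥ 0.75,
consensus-side coverage ≥ 0.20, score ≥ 0.75 × self-match score. Whether
the original procedure required these in one direction or both is
ambiguous; we test the single stated direction (profile side = larger
cluster in the default scorer). Profile scoring itself is pluggable: the
bundled `similarity_profile_scorer()` works from the edge list alone and
is documented as a desk-scale stand-in, not a profile-HMM equivalent.
Merging is a union–find over passing edges, so the result is always a
coarsening of the MCL partition. A species-composition sanity flag
(`flag_species_dominated()`, > 90% one species) is provided in place of
upstream contamination removal, which is out of scope.

## Marker filters

Four bespoke filters precede species-tree inference from single-copy
markers; alignment, trimming and tree inference themselves are out of
scope. `remove_terminal_duplicates()` collapses maximal same-species
clades to one representative — the copy with the smallest mean distance
to other species when distances are supplied, else the lexicographically
smallest label (the original script does not document its rule); the
operation is idempotent and never removes a species' last leaf.
`mean_distance_filter()` rejects alignments with mean pairwise distance
≥ 1.5. `ancestral_paralog_screen()` builds an average-linkage hierarchy
and fails a marker when both sides of the first split share at least two
species — one operational reading of "low phylogenetic relations at the
first split", flagged as an interpretation. `alignment_size_filter()`
keeps alignments ≥ 60 residues covering ≥ 30 species. A Poisson-corrected
distance (`-ln(1 - p)`) is bundled as the default stand-in when no
model-based distances are supplied.

## Reconciliation and Dollo mapping

Gene trees are rooted by exhaustive search over branches, minimizing
duplications + losses under LCA reconciliation; ties prefer fewer
duplications, then the lexicographically smallest root bipartition.
Supports are keyed by the bipartition they annotate, so rerooting cannot
misplace them; edges with support below 80 are contracted into polytomies
before reconciliation. At a polytomy we label a duplication only when it
is forced — some child co-maps with the node, or two children map to the
same species-tree node — rather than attempting rearrangement. Orthogroups
are the maximal speciation-only subtrees obtained by cutting below every
duplication node.

Dollo mapping places each family's single gain at the MRCA of its
carriers and one loss on the root branch of every maximal carrier-free
subtree below the gain. Species absent from a family contribute losses
only below the gain node, matching Dollo semantics — there is no
"unsampled" state. Ancestral copy numbers within the surviving clade are
reconstructed by integer L1 parsimony (dynamic programming over copy
states 1..max observed; states 0 are reserved for lost subtrees so a
family can never reappear after loss). Ties are resolved toward the
parent's value, and toward 1 at the gain node, which avoids manufacturing
duplication–loss pairs the data do not demand; the original
implementation does not print its tie rule. Both per-copy (`"counts"`)
and presence-only (`"presence"`) reconstructions are available, since the
source is ambiguous about which it maps; `aggregate_events()` exposes the
choice.

Per branch, a copy-number increase of *d* is *d* duplications, a decrease
*l* losses, and a branch into a lost subtree loses all of its parent's
copies (one loss in presence mode). This makes the bookkeeping identity
`copies(node) = copies(parent) + gains + duplications − losses` an exact
integer identity at every node, which the tests assert on every run, and
makes event maps additive over family sets.

Two properties calibrate expectations on real data: with no losses the
reconstruction recovers simulated truth exactly, and with losses the
inferred gain can postdate but never predate the true origin — Dollo
places gains at the MRCA of *surviving* carriers, so families whose early
branches died out look younger than they are. Ancestral proteome sizes
inherit this bias and should be read as lower bounds in loss-heavy
regimes.

## Repertoire classifiers

All classifiers are pure functions of annotation tables (domain content,
predicted localization with score, length, signal-peptide/transmembrane
flags, GO terms); the external predictors that produce those tables are
out of scope. Thresholds follow the stated rules, with boundaries as
worded per rule: the majority rule is strict (> 50%), while the 70%
conservation, 75% fungal-domain, and 99% domain-specificity rules are
inclusive ("at least"); the SSP length bound is strict (< 300 aa) and the
plasma-membrane score is strict (> 15). For transporters, "most likely
localization within the HG" is made operational as the mode over members
(ties conservatively fail) with the score aggregated as the median — the
source does not specify the aggregation. Novel-core families must be
gained strictly after the reference ancestor and conserved in ≥ 70% of
the species descending from their own gain node; protist-conserved lost
families must be present in the focal ancestor under Dollo, absent from
the derived clade, and conserved in ≥ 70% of at least one species group
or of early origin.

Dynamics ranking sums, along a root-to-descendant chain of nodes, the
per-branch relative net change `(copies(child) − copies(parent)) /
max(copies(parent), 1)`; the clamped denominator means a family newly
gained on the path contributes its copy count. "Across eight nodes" can
be read as 8 nodes or 8 branches; the function takes the node chain
explicitly (9 nodes = 8 branches being the natural reading), so the
caller controls the path. Repertoire diversity uses the Shannon index
with natural logarithm (no base is stated in the source).

## Ordination and enrichment

HGs entering the ordination need ≥ 4 member proteins and ≥ 50%
conservation in at least one clade; the clade set is an input, not
hard-coded. The binary distance is the Jaccard complement `(b + c) / (a +
b + c)` — the default "binary" distance of the R dist machinery the
original analysis used — with the degenerate all-absent species defined
as distance 0 to an identically empty species and 1 otherwise. PCoA is
classical scaling; negative eigenvalues are reported but never used for
coordinates (no Cailliez correction — the distances here are near-metric
and correction would dilute the axes' variance shares). The minimum
spanning tree uses Kruskal with lexicographic tie-breaking so plots are
reproducible. Enrichment is the one-sided hypergeometric (Fisher) test
with raw p < 0.05 as the significance rule, as in the source; a
Benjamini–Hochberg column is optional and off by default. The
`weight01`-style decorrelation is approximated by the `elim` variant
(significant terms' genes removed from their ancestors before those are
tested); rankings can differ from true weight01 output, which is noted
here deliberately.

## The synthetic-data generator

The source infers histories but does not simulate; every distributional
choice in the generator is therefore a validation stand-in, chosen once:

* Species trees are pure-birth (Yule) — the standard neutral shape model.
* Each family originates exactly once, at a node drawn uniformly by
  default (`"root"` and branch-length-weighted `"branch"` modes exist;
  root-only gives clean Dollo test cases). Horizontal transfer is not a
  separate event type; like the source, we fold it into origination.
* Per branch, duplications and losses are Poisson with mean `rate ×
  copies(parent) × branch length` — the simplest process matching
  per-branch event counts; losses are truncated at available copies.
  Duplications may fall on the origin's own branch, so an origin starts
  at `1 + duplications`.
* Similarity graphs are planted partitions: intra-family edges dense
  (probability 0.9) and strong (scores ~ N(200, 20), e-values 1e-60 to
  1e-20), inter-family edges sparse (0.02) and weak (N(40, 4), e-values
  1e-6 to 1e-1, straddling the 1e-4 filter); 10% of edges draw a
  short-side coverage below 0.8 so the coverage filter is exercised.
  These rates define the study conditions for clustering recovery.
* Annotation tables are generated per family from a profile of domain /
  localization / signal-peptide / length / GO probabilities, with 5%
  localization-prediction noise, so families that are exactly "TF",
  "transporter" or "SSP" by the rules can be planted.

What the generator does **not** emulate: sequence evolution (no
alignments or realistic score distributions), rate heterogeneity across
families and branches, correlated losses, contamination, fragmented gene
models, or annotation error structure beyond independent Bernoulli noise.
Passing tests therefore demonstrate correctness of the *inference logic*
under known truth, not robustness to the failure modes of real proteome
data.

## Problem sizes and numerical tolerances

The validation suite runs at desk scale, chosen to exercise every code
path while keeping a full run in minutes: exhaustive Dollo checks cover
all tree shapes with ≤ 6 tips (511 shape × pattern combinations);
bookkeeping and origin-recovery checks use 20-tip trees with 1,000 and
10,000 simulated families; clustering recovery uses the 10-family ×
8-protein planted design over 20 seeds; the Fisher test is compared with
an exact tail sum on all tables with totals up to 50 (≈ 315,000 cases, to
1e-12); PCoA must reproduce embeddable distances to 1e-9. The same
quantities are recomputed end to end by `scripts/acceptance.R`.

## A small end-to-end run

```{r example}
tree <- simulate_species_tree(8, seed = 1)
sim <- simulate_gene_content(tree, n_families = 100,
                             duplication_rate = 0.2, loss_rate = 0.2,
                             seed = 2)
em <- aggregate_events(sim$counts, tree)
glance(em)
check_event_bookkeeping(em)

ord <- gc_pcoa(binary_distance(sim$counts))
glance(ord)
```

## Known limitations

* Dollo parsimony underestimates family age and ancestral content when
  losses are heavy (see above); it cannot represent regain.
* The default profile scorer is a stand-in for profile-vs-consensus HMM
  scoring; merge decisions on real data should use a real profile tool
  behind the same interface.
* Polytomy reconciliation is conservative and does not rearrange weakly
  supported regions; duplication counts are lower bounds there.
* `elim` is not `weight01`; enriched-term *sets* agree in the regimes we
  test, rankings need not.
* The pipeline orchestrator is deliberately thin: it chains the stages on
  synthetic data and writes a manifest; real-data runs are expected to
  call the stage functions directly.
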