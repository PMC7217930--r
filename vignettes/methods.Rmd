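---
title: "Methods: evidence-filtered knowledge networks and the repositioning cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-filtered knowledge networks and the repositioning cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reponet)
```

`reponet` implements a network-medicine drug-repositioning analysis:
starting from tabular association evidence between genes, drugs and a
family of related diseases, it builds evidence-filtered knowledge
networks, characterizes disease similarity through network modules and
exact overlap tests, identifies disease-exclusive co-expression hub
genes, and runs a multi-filter cascade that proposes drugs targeting
exactly one such gene with no prior indication in the disease family.
This vignette documents the statistical model behind each stage, the
tunable parameters, the numerical conventions, and the limits of what
the synthetic benchmarks demonstrate.

## Association evidence and the retention filter

Two evidence dialects are supported. *Literature* records emulate
text-mining output: each subject–object assertion carries `n_documents`
(count of supporting documents, ≥ 0) and `confidence` (a percentage in
[0, 100]). *Score* records carry a single overall association score in
[0, 1], the convention of public target–disease platforms. A record
table holds exactly one dialect; duplicate (subject, object) rows merge
keeping the maximum of each evidence field independently, which is
conservative toward retention and is logged for audit.

The retention rule (`filter_associations()`) keeps literature records
with `n_documents >= 2` **and** `confidence > 50` (strict), and score
records with `score > 0.5` (strict). The strictness of each boundary
matters — a record at exactly 50% confidence, one document, or score
0.5 is dropped — and the test suite pins every boundary. All three
thresholds are exposed as arguments because different corpora calibrate
confidence differently; the defaults are the protocol values the
analysis was designed around.

Entity labels are normalized at load: gene symbols are upper-cased,
drug and disease names are whitespace-trimmed with case preserved, and
an optional two-column synonym table is applied before validation, so
that synonym redundancy in the raw exports does not inflate the
networks.

## Knowledge networks, exclusivity

Filtered records of one kind-pair become an undirected bipartite graph:
one node per distinct entity, one edge per surviving record, evidence
carried as edge attributes. Edges are *unweighted* for topology
(community detection and overlap statistics); no weighting scheme is
imposed because document counts and confidences are not comparable
across corpora.

A gene is *exclusive* to a disease when it is associated with that
disease and no other disease **present in the input**. Exclusivity is
deliberately relative to the queried disease set, not to any global
disease universe — the question the cascade asks is "specific within
this disease family", not "specific in all of biology".

## Louvain modularity optimization

Community detection maximizes Newman–Girvan modularity with resolution
γ (default 1):

$$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \gamma\frac{k_ik_j}{2m}\right)\delta(c_i,c_j).$$

The implementation is the classic two-phase greedy scheme: local moving
(each node is moved to the neighbouring community with the largest
positive ΔQ until a full sweep makes no move) alternating with graph
aggregation, until modularity stops improving. Modularity is asserted
non-decreasing across levels inside the algorithm. Self-loops created
by aggregation follow the A_ii = 2w degree convention, so the
modularity of an aggregated partition equals that of its expansion
exactly.

Determinism and search quality are handled together: node visiting
order is a seeded shuffle, ΔQ ties are broken by a seeded random draw
among the tied communities, and `louvain()` runs `n_restarts`
independent orderings, returning the best-Q partition. The default is
200 restarts for graphs of up to 12 nodes and 20 otherwise: on very
small graphs each run costs microseconds and most orderings fall into
the same basin of attraction, so restarts are where the quality comes
from. Random tie-breaking (rather than a fixed preference such as the
lowest community id) is essential for basin diversity: with a
deterministic preference, measured on small benchmark graphs, every
ordering can converge to the same suboptimal partition.

`brute_force_partition()` enumerates all set partitions (feasible to 10
nodes, Bell(10) = 115 975) and is the exact oracle in the tests. Ties
are broken toward fewer communities, then the lexicographically
smallest restricted-growth labelling.

**Known limitation.** Louvain is a greedy heuristic and some small
graphs have local optima no ordering escapes: the suite contains an
8-node, 12-edge example whose optimum (Q = 1/6) requires a coordinated
two-node swap, where both this implementation (200 orderings) and the
independent igraph implementation (500 runs) always return Q ≈ 0.153.
On 100 random graphs of up to 8 nodes under the suite's fixed
generation seed, the restart scheme attains the exact brute-force
optimum on every graph; users should expect occasional ~92% ratios on
adversarial small graphs, and essentially optimal behaviour on graphs
with real community structure (the planted-cluster benchmarks below).

Community detection runs on the unipartite view of the bipartite
network — diseases and their genes share modules — with no
bipartite-specific null model, matching how mixed-kind modules are read
in this kind of analysis.

## Exact overlap significance

The significance of the overlap k between two entity sets of sizes K_a
and K_b in a universe of N is the one-sided upper hypergeometric tail

$$p = P(X \ge k),\qquad X \sim \mathrm{Hypergeom}(N, K_a, K_b),$$

evaluated on the log scale via `lchoose` and summed from the top of the
support so small tails lose no precision (agreement with direct
enumeration is ≤ 1e−10 over every table with N ≤ 40; the realized
maximum difference is ~8e−15). One-sided enrichment is the default
because overlap *excess* is the hypothesis of interest; a two-sided
mode (summing all tables with point probability not exceeding the
observed, the standard exact-test convention) is available.

The universe defaults to the union of all entity sets in the analysed
network — the only self-contained choice; it is recorded in the result
attributes and overridable. Significance uses a raw strict p < 0.01
cutoff with no multiple-testing correction, matching the protocol this
implements; `adjust_overlap()` provides Benjamini–Hochberg for users
who want it. Results are reported as −log₁₀ p.

## Enrichment with a permutation combined score

Per term, the over-representation p-value is the same exact
hypergeometric tail (a single shared implementation — the tests assert
bit-identity with `fisher_overlap()`). The combined score multiplies
−ln p by a rank-deviation z-score: terms are ranked by p for the
observed query and for `n_permutations` random queries of the same
size, and

$$z = \frac{\bar r_{\mathrm{perm}} - r_{\mathrm{obs}}}{\mathrm{sd}(r_{\mathrm{perm}})},
\qquad \mathrm{combined} = -\ln(p)\, z.$$

The z-null is generated by explicit seeded permutation rather than a
precomputed lookup table, so results are self-contained and
reproducible; `n_permutations` (default 1000) and the seed are stored
on the result. Terms with zero overlap are reported with p = 1 and
combined score 0, never silently dropped. Retention keeps terms with
combined ≥ 20 (inclusive) and p < 0.01 (strict). Degenerate cases: a
zero rank-sd yields z = 0; `n_permutations = 0` disables the z
computation, which is how the type-I calibration benchmark isolates the
p-values (≤ 1.2% of terms at p < 0.01 over 1000 random queries —
conservative, as expected for a discrete one-sided test).

## Eigengenes, kME and hubs

Expression is standardized gene-wise to mean 0, sd 1 with the sample
(n−1) denominator — the dominant convention, pinned for bit-stability.
A module's *eigengene* is the first right-singular vector of the
standardized member submatrix: a unit-norm, sample-indexed summary
whose sign is aligned so the mean Pearson correlation with member genes
is non-negative (singular-vector sign is otherwise arbitrary, and tests
need determinism). Explained variance is d₁²/Σdⱼ².

kME (module membership) is the Pearson correlation between a gene's
**raw** profile and its module's eigengene — eigengene on standardized
data, kME on raw profiles, the WGCNA convention; both choices are
configurable points in the code and documented because the upstream
convention is not always stated alongside published module tables.
Hubs are genes with kME > 0.5 (strict) in their own module.
Zero-variance genes are dropped with a warning (kME undefined).

Under the planted model (below) a member gene is
λf + σε with λ = 0.8, σ = 0.6, so its population correlation with the
latent factor is λ/√(λ²+σ²) = 0.8; the suite verifies the realized mean
kME ≈ 0.8 at 10 000 samples and, at the benchmark size of 50 samples,
≥ 95% hub recovery for members with ≤ 5% false calls among pure-noise
background genes.

Module *discovery* is out of scope: assignments are an input, because
the analysis consumes published co-expression module tables rather than
re-deriving them.

## The repositioning cascade

The cascade stages, in order, with their audit semantics:

1. gene–disease and drug–disease records pass the evidence filter;
2. the gene network yields per-disease and exclusive gene sets;
3. kME hub calling on the expression input;
4. target genes = exclusive ∩ hubs, per disease (exclusivity computed
   *before* the hub intersection — matching the order in which the
   selection is described; diseases with an empty result are retained
   and logged);
5. drug–gene records pass the **same** evidence thresholds, and rows
   whose gene is a target emit (drug, gene, disease) candidates;
6. removals: (i) drugs linked to *any* study disease in the filtered
   drug–disease table — repositioning within the family requires no
   prior family indication; (ii) drugs whose surviving rows span more
   than one distinct **selected** gene (the search was restricted to
   the selected genes, so that is the visible scope of "multi-gene");
   (iii) drugs on a machine-readable exclusion list, the reproducible
   stand-in for manual document curation;
7. trial annotation by left-join on the canonical drug name (multiple
   trials sorted and semicolon-joined; unmatched rows "none found").

Every drug in the raw drug–gene input is accounted for in exactly one
place: the retained table, or the removal log with one reason drawn
from `below_evidence_threshold`, `gene_not_target`, `known_pnd_drug`,
`multi_gene`, `manual_exclusion` (applied in that priority order when a
drug violates several). Retained candidates are ranked by evidence
strength — documents descending, then confidence (or score) descending,
dense ranks, ties in the output file broken by drug name — a
deterministic choice made here because no ranking rule is inherited.

A note on monotonicity: the drug–gene search stage is monotone in the
evidence thresholds (raising `min_documents` never adds surviving
rows), and the suite asserts this with the first-stage outputs held
fixed. The *end-to-end* pipeline is deliberately not monotone: a
stricter threshold also prunes the drug–disease table (fewer "known"
drugs) and can flip gene exclusivity in either direction, so whole-run
monotonicity is neither true nor asserted.

## What the synthetic generator emulates

`generate_knowledge_corpus()` plants: disease clusters (default: nine
diseases in four pairs plus one singleton, mirroring a study of
related disorders) whose members share a fraction (default 0.5) of a
per-group gene pool; exclusive genes per disease; background genes with
no association; known drugs with 1–3 disease links; planted candidates
(one passing drug–gene record to a single exclusive co-expressed gene,
no disease link); and decoys violating exactly one filter each.
Evidence values sit deliberately around the thresholds: passing records
draw confidence uniformly on (51, 100] and 2–10 documents; failing
records sit *just* below a boundary (confidence exactly 50, or exactly
one document; score exactly 0.5) to pin strictness. `evidence_noise`
adds sub-threshold cross-group records at rate noise/(true+noise), so
the filter must remove them for the planted structure — including
exclusivity — to be recovered.

`generate_expression()` draws one latent standard-normal factor per
module and member genes as λf + σε, background genes as pure noise.
All randomness flows from a single master seed through a stage-name
splitting scheme (`split_seed()`), so corpora, expression and Louvain
restarts are reproducible independently.

What the generator does **not** emulate: text-mining noise models and
document semantics, realistic degree distributions (attachment within
pools is uniform — declared, not inferred), correlated evidence between
record types, batch structure or heavy tails in expression, and
overlapping co-expression modules. Passing the planted-recovery
benchmarks therefore demonstrates that the *logic* of the cascade is
correct and strict at every boundary — not that the thresholds are
well-calibrated for any particular real corpus.

## Problem sizes and runtime choices

The bundled benchmarks use sizes chosen to exercise every code path
while keeping the whole suite interactive: exhaustive hypergeometric
verification to N = 40; Louvain oracles on 100 graphs of ≤ 8 nodes
(Bell(8) = 4140 partitions each); kME recovery with two 30-gene modules,
200 background genes, 50 samples, 20 seeds; enrichment calibration with
a 200-gene universe, 40 terms, 1000 queries; and 20 synthetic corpora of
nine diseases, ~300 gene–disease records each, for end-to-end recovery.
`scripts/acceptance.R` recomputes all of these from scratch in about a
minute.

## Known limitations

- Louvain local optima on adversarial small graphs (measured example
  above); restarts mitigate but cannot guarantee the global optimum.
- The hypergeometric universe choice materially affects p-values; the
  self-contained default (the network's own entity catalogue) is
  smaller than a genome-wide background and therefore conservative for
  overlap enrichment between large sets.
- The permutation z in the combined score is Monte-Carlo noisy at small
  `n_permutations`; rankings near the retention boundary should be
  read with that in mind.
- Exclusivity is relative to the queried disease set: adding a disease
  to the input can only shrink exclusive sets.
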