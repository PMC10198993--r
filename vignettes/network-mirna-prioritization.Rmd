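---
title: "Network-based prioritization of compound targets and regulatory microRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based prioritization of compound targets and regulatory microRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfish)
library(dplyr)
```

## The problem and the pipeline

Natural-product pharmacology often starts from a phenotype — a compound kills
a cancer cell line — with no mechanism attached. mirfish implements one
widely used computational route from compound to mechanism hypothesis, as a
chain of small, testable stages:

compound → structurally similar compounds → their protein targets →
protein–protein interaction (PPI) network → hub protein → miRNAs predicted to
regulate the hub → accessibility- and stability-filtered miRNA candidate.

The packaged fixtures carry the endpoint tables of a published analysis of
this kind (the flavonoid pinostrobin in acute leukemia cells, converging on
the DNA-damage kinase ATM and miR-181b-5p), so the whole chain can be run and
checked offline. This vignette explains each stage's model, the tunable
parameters and their defaults, the synthetic-data design, and the numerical
choices.

## Stage models and assumptions

### Ligand-based target fishing

The similarity principle: structurally similar compounds tend to share
targets. Similarity is Tanimoto over bit-set fingerprints,
$T(A,B) = |A \cap B| / |A \cup B|$. The packaged fingerprint is a
substring-hash scheme — every contiguous substring (length ≤ 8 by default) of
the structure string is hashed (base-31 polynomial modulo the prime
16777213, then modulo the width, 2048 bits by default) — chosen because it is
fully deterministic, dependency-free and documented; it behaves like a path
fingerprint but is *not* ECFP, so absolute similarity values differ from any
particular cheminformatics backend. `fish_targets()` also accepts
fingerprints built elsewhere via `new_fingerprint()`.

Filters follow the printed wording of the reference analysis exactly:
similarity strictly greater than 0.7, potency strictly below 150 µM, organism
`"Homo sapiens"`. Records with unknown potency are excluded — the
conservative reading, since the potency criterion cannot be verified for
them. Two empty fingerprints get similarity 0, never 1: structureless inputs
must not match. Because the upstream compound database's fingerprint is
unspecified, the 25-target endpoint table is shipped as a fixture rather than
re-derived from raw chemistry; the target-fishing stage is validated on
libraries engineered so that exactly those targets pass.

### PPI network construction and scale-free selection

Interactomes arrive as STRING-format TSV (`protein1 TAB protein2 TAB
combined_score`). Scores on STRING's 0–1000 integer scale are auto-detected
(any value > 1) and divided by 1000; edges at or below the confidence floor
(default 0.4, exclusive) are dropped; duplicate undirected edges keep the
maximum score.

`expand_network()` mimics interactor-shell expansion: the first sphere adds
the `first_sphere` non-seed proteins with the largest summed edge score to
the seed set; the second sphere adds `second_sphere` new neighbors of the
first shell, ranked by summed score to the expanded set. The upstream
server's own ranking heuristic is not published, so summed edge score with
lexicographic tie-breaking was chosen: it is monotone, deterministic, and
reduces to "strongest cumulative evidence first". Seeds absent from the
interactome are kept as isolated nodes (and excluded from degree fits, since
degree 0 has no logarithm).

Scale-freeness is scored exactly as practitioners do in Cytoscape: ordinary
least squares of $\log P(k)$ on $\log k$ over the distinct observed degrees
$k \ge 1$, with $P(k)$ the fraction of nodes of degree $k$; $\gamma$ is minus
the slope and R² the selection criterion. No binning, no zero-count degrees,
and deliberately no maximum-likelihood (Clauset-style) estimation — the R²
criterion *is* the method being reproduced. `select_network()` takes the
candidate grid's maximum R², breaking ties by smaller node count then
lexicographically smallest settings (parsimony).

### MCC hub ranking

Maximal Clique Centrality scores each node by
$\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$ over the maximal cliques $C$ of
the unweighted topology (edge scores are ignored; a clique is a purely
topological object). Cliques come from an in-package Bron–Kerbosch
enumeration with pivoting; `igraph`'s independent implementation serves as a
cross-check in the tests, alongside a brute-force subset-enumeration oracle.
Because $(|C|-1)!$ exceeds exact double precision already at $|C| = 20$,
scores are accumulated in exact integer arithmetic (a small base-10⁴ limb
representation); the ranked table reports both the exact decimal string and a
double approximation. An isolated node scores 1 — its singleton is its only
maximal clique and $0! = 1$ — and is flagged, since conventions for edgeless
nodes differ between tools. Ties in the ranking break by higher degree, then
symbol.

The top-`k` hubs (default 10) are intersected, order-preserved, with an
annotation set (default term `"apoptotic process"` from a two-column
symbol/term TSV). Enrichment statistics are out of scope: the stage is a set
intersection, as in the reference analysis.

### miRNA prediction consensus

Four predictor export dialects are mapped onto one schema by a packaged,
editable YAML column map. Per-tool filters follow each tool's printed
criterion, including strictness:

| tool | rule | boundary |
|---|---|---|
| DIANA-microT-CDS | miTG score ≥ 0.7 | 0.7 passes |
| miRDB | prediction score > 80 | 80 fails |
| TargetScanHuman | context+ ≤ −0.1 **or** P_CT ≥ 0.5 | both boundaries pass |
| RNA22 | p < 0.05 | 0.05 fails |

Tools emit several sites per miRNA; the consensus treats miRNAs as units, so
each miRNA is judged on its best record per tool (max score fields, min
p-value/context+). Identifiers are matched case-insensitively with the
`hsa-` prefix normalized on. A miRNA is kept when it passes in at least
`min_tools` (default 3) of the four tools, and the full 15-cell Venn
decomposition is reported with every miRNA counted once in its exact
membership cell — so any bookkeeping discrepancy in a published Venn figure
is diagnosable from the report.

### Site accessibility and candidate ranking

Partition-function folding servers summarize a 3′UTR as a per-nucleotide
single-strandedness probability; that profile is consumed as input (the
folding computation itself is out of scope). An *accessible region* is a
maximal run of positions with probability strictly greater than 0.5 — at
exactly 0.5 a position is closed. A candidate site counts as accessible when
it overlaps any region by at least `min_overlap` nucleotides (default 1,
configurable), the weakest reading of "can hybridize with the accessible
region"; the reference analysis does not define the overlap extent, and its
14 printed candidates are all accessibility-positive under any overlap rule
by construction of the fixture profile.

Final ranking must satisfy a double criterion — highest binding likelihood
(LogitProb, a logistic-model score consumed as input, never recomputed) *and*
lowest hybrid free energy (∆G, kcal/mol). The two orders can conflict in
general, so candidates are aggregated by rank-sum (competition ranks;
descending LogitProb plus ascending ∆G), with ties broken by higher LogitProb
then id. A candidate dominant on both axes always wins, so the rule
coincides with the double criterion whenever that criterion is consistent —
on the packaged tables it is.

`duplex_dg()` provides a simplified nearest-neighbor hybrid energy for
synthetic candidates and property tests: initiation penalty plus the sum of
Watson–Crick stack energies (the 16 ordered pair steps of the Turner/Xia 1998
parameter set, packaged with source citation). Loops, bulges, dangling ends
contribute nothing, and stacks involving a G:U wobble (accepted as a pair)
contribute 0. The ∆G values in the packaged candidate table are inputs for
ranking and are never recomputed by this model.

### RT-qPCR utility

`relative_expression_ddct()` implements the standard
$2^{-\Delta\Delta C_T}$ relative quantification used to verify predictions
downstream; it is a one-line convenience, vectorized over replicates.

## Synthetic data: what it emulates, what it does not

The generators exist so that every stage has positive and negative controls
with known ground truth:

* `gen_ppi_network()` draws Barabási–Albert preferential-attachment networks
  (connected, heavy-tailed; the positive control for the power-law fit) and
  Erdős–Rényi networks (binomial degree law; the negative control). Edge
  scores are uniform in (0.4, 1], i.e. strictly above the default confidence
  floor, so generated graphs pass the read filter unchanged — positive
  controls are filter-invariant by design.
* `gen_prediction_tables()` plants `n_planted` miRNAs with passing scores in
  three or four tools; each other pool member emits, with probability
  `noise_rate`, decoy rows guaranteed to fail — either support in ≤ 2 tools,
  or scores missing every threshold by at least 0.01 of the threshold scale
  (the margin removes floating-point boundary flakiness). At
  `noise_rate = 0` the consensus equals the planted set exactly; that
  noiseless identity, and planted-set recovery under noise, are asserted in
  the tests.
* `gen_accessibility_profile()` draws probabilities in (0.55, 0.95) inside
  the planted windows and (0.05, 0.45) outside, again with margins around
  the 0.5 threshold, so region recovery is exact by construction.

Defaults (`synthetic_spec()`: 100 nodes, attachment 2, ER p 0.1, 100 miRNAs,
10 planted, noise 0.2, 3000-nt profile) are sized like the real problem —
tens of proteins, low hundreds of predicted miRNAs, a few-kilobase 3′UTR —
while keeping the full test suite under a minute. All generators are seeded
through the spec and byte-reproducible.

What passing synthetic tests does **not** show: real predictor score
distributions (the generators sample uniforms within pass/fail bands, not
tool-specific shapes), real interactome topology (BA graphs lack STRING's
cliquishness), or real compound bioactivity structure (the fingerprint
library tests use structural toys). The synthetic controls validate the
*logic* of each filter, not the biology of any particular dataset.

## Packaged fixtures

Four fixtures transcribe printed endpoint tables verbatim: the 25 predicted
targets, the 14 candidate miRNA sites (positions 1-based inclusive, signed ∆G,
with evidence flags for the five literature-supported miRNAs), the top-10
MCC hub list, and the 14-protein apoptosis set. Their checksums are frozen in
the tests.

Three fixtures are synthetic stand-ins, labelled as such in their filenames,
because the corresponding raw inputs were never deposited: the interactome
(no published edge list exists; the stand-in is constructed so that expanding
the 25 seeds by a first sphere of 10 yields the printed 35-protein,
110-interaction network, with the ten added proteins being the eight
non-seed hubs of the printed top-10 plus the two apoptosis-set proteins
absent from the seed list, and so that ATM is the top MCC hub), the four
predictor exports (constructed so the consensus keeps 22 miRNAs: the 14 real
candidates plus 8 decoys whose sites avoid every accessible region, matching
the printed 22 → 14 funnel), and the accessibility profile (generated with
accessible windows equal to the merged candidate site ranges, since all 14
printed candidates hybridize to accessible regions). Conclusions about
counts downstream of these fixtures are checks of the pipeline's mechanics
against the printed funnel, not independent re-derivations from raw data.

The published Venn arithmetic upstream of the 22-miRNA stage (73 consensus
miRNAs described as 12 + 51) does not sum; the package does not attempt to
reproduce those three numbers, and the consensus report makes every Venn
cell explicit precisely so such discrepancies surface.

## Numerical choices and degenerate inputs

* All threshold comparisons honour printed strict/non-strict wording; the
  boundary behaviour is pinned by tests.
* Power-law fits require ≥ 2 distinct positive degrees; complete and empty
  graphs raise a degenerate-fit error rather than returning a fake R².
* Factorials in MCC are exact integers at any clique size; ranking compares
  exact values.
* Clique enumeration, expansion ranking and hub ordering are fully
  deterministic (sorted outputs, documented tie-breaks), so reports are
  byte-reproducible for a fixed config.
* `tanimoto()` on two empty bit sets is 0 by convention (avoids 0/0).
* Duplex pairings must be non-crossing and antiparallel; non-complementary
  pairs are errors, not zero-energy stacks.

## Problem sizes in the test suite

The oracle-equivalence tests run the brute-force subset enumeration on 200
random graphs of 4–10 nodes; synthetic consensus tests use pools of 30–100
miRNAs; profile tests use 50–500-nt profiles; the BA positive control uses
200 nodes. These sizes make every oracle exhaustive (the clique oracle
enumerates all 2^n vertex subsets) while the whole suite stays fast.

## Known limitations

* The fingerprint is a documented toy; reproducing a particular database's
  "70% similarity" hit list requires plugging in that database's own
  fingerprints via `new_fingerprint()`.
* The duplex model has no loop, bulge, dangling-end or G:U stack terms; its
  ∆G values are comparable within this package only.
* OLS-on-log-log is known to be a statistically weak estimator of power-law
  exponents; it is implemented because it is the method being reproduced,
  not because it is recommended for new analyses.
* GO annotation is consumed as a flat symbol/term table; no ontology
  traversal or enrichment testing.
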