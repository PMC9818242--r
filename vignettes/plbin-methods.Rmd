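---
title: "Prediction-logic Boolean implication networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction-logic Boolean implication networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plbin)
```

This vignette is the package's account of the science it implements: the
categorization models, the prediction-logic scoring of implication rules,
the statistical conventions chosen where several were defensible, what the
synthetic generators do and do not emulate, and the limitations we know
about. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Categorizing molecular measurements

### Expression (ternary, housekeeping-calibrated)

Bulk expression and protein abundances are continuous and log-scaled;
implication rules need down / normal / up states. The package calibrates
the state boundaries on a housekeeping panel — genes whose expression is
biologically stable — so that a fixed total fraction of samples
(`target_outside`, default 0.30) falls outside the normal range across the
panel:

1. per housekeeping gene, quantile cutoffs at `target_outside/2` and
   `1 - target_outside/2` (linear-interpolation quantiles by default,
   nearest-rank selectable) bound its normal range;
2. the sample SD (n−1) of the values strictly inside the cutoffs is that
   gene's normal-range SD; their mean is `sigma_bar`, the width unit
   shared by the whole genome;
3. a half-width multiplier is calibrated by bisection so that
   re-categorizing the housekeeping panel with half-width
   `multiplier * sigma_bar` around each gene's center reproduces the
   target outside fraction. The outside fraction is a step function of the
   multiplier, so the calibration is exact only up to the data's
   granularity (1 / panel-value count); a warning reports misses beyond
   0.5 percentage points.

Design choices that the method leaves open and we fixed: the 30% outside
mass is split symmetrically (15% up, 15% down) — the split is the natural
symmetric default and configurable through the quantile pair; the
per-gene center is the **median** (translation-equivariant and robust;
mean selectable); boundary values are classified **normal** (deterministic
and conservative); the multiplier is calibrated on the housekeeping panel
itself rather than fixed at 1, which makes the 30% target self-consistent
whatever the panel's SD happens to be. Whether the original software
centers on mean or median, and whether its split is symmetric, is not
documented; protein data are treated with mechanics identical to mRNA.

### Copy number, single-cell counts, drug response, essentiality

* CNV states: deletion below 2 copies, normal at 2, duplication above 2.
  The rule is stated for integer copy-number calls; real-valued estimates
  require an explicit tolerance (`normal iff |CN − 2| <= tol`) so that the
  user, not the package, owns that rounding decision.
* Single-cell counts: dropout makes graded categorization unreliable, so a
  gene is "expressed" in a cell iff its feature count exceeds 0.
* Drug response: IC50/EC50 above the maximum tested dose is resistant,
  below the minimum dose sensitive; the in-range remainder is split at its
  mean ± 0.5 sample SDs into sensitive / partial / resistant, boundaries
  partial. The band is computed on the values as given (an optional log10
  mode exists; the original scale is not documented).
* Dependency scores (normalized so non-essential medians sit at 0 and
  essential medians at −1): an effect is significant strictly below −0.5.

## 2. Prediction-logic scoring

For a gene pair with contingency counts $N_{ij}$, margins $N_{i\cdot}$,
$N_{\cdot j}$ and total $N$, a rule with error-cell set $\omega$ has

$$U_p = \sum_{(i,j)\in\omega} \frac{N_{i\cdot} N_{\cdot j}}{N^2}, \qquad
\nabla_p = 1 - \frac{K/N}{U_p}, \qquad K = \sum_{(i,j)\in\omega} N_{ij}.$$

The cell-weighted form
$\nabla_p = \sum_\omega (U_{ij}/U_p)\,\nabla_{ij}$ is algebraically equal
to the closed form; the suite verifies the identity to $10^{-12}$ on 1,000
random tables.

**Error-cell semantics.** Under the default *strict* semantics a cell is
an error when the antecedent holds and the consequent does not — for
ternary data the NORMAL state fails an UP or DOWN consequent. *Lenient*
semantics counts only outright contradictions (NORMAL-containing cells are
removed). The original figure defining the cell layout is not recoverable
from text, so both are implemented; for binary variables they coincide.
EQUIVALENT and OPPOSITE are the unions of an asymmetric template with its
transpose, matching the definition of the symmetric relations as two
implications holding at once.

**The z test.** The selection thresholds are derived from a one-tailed z
test at a preset value (default 1.645, the smallest value used for
network construction). The published description does not give the test
statistic, so we model the error count under independence as
$K \sim \text{Binomial}(N, U_p)$ and use
$z = (N U_p - K)/\sqrt{N U_p (1-U_p)}$. Because $U_p$ is estimated from
the same margins that generate $K$, the two are positively correlated and
the test is conservative: its null rejection rate, measured by the suite
on 2,000 independent ternary pairs at $n = 200$, sits far below the
nominal 5%. We keep the simple binomial form because it is monotone in
the evidence, needs no resampling, and errs on the side of fewer false
edges.

**Feasibility and guards.** A rule can only reach the preset z if
$U_p \ge z^2/(N + z^2)$ (set $K=0$ and solve); scopes below that bound are
infeasible regardless of the data. `rule_stats()` and `select_rule()`
report the bare statistic (`min_expected = 0`) so that small worked
tables evaluate exactly as printed; `induce_network()` additionally
requires $N U_p \ge 5$ (the usual normal-approximation floor) and at
least `min_n = 10` retained samples per pair — at genome scale millions
of pairs are tested and the approximation must hold where it is used.
This split is deliberate: the statistic level is exact bookkeeping, the
network level is mass inference.

**Selection.** `precision_first` (default) returns the significant
template with the highest precision, ties broken by larger scope, then by
the fixed template order — fully deterministic. `strict_dominance`
returns a template only when it maximizes both precision and scope
simultaneously, which is frequently unattainable (a specific rule often
beats a symmetric one on precision while losing on scope), hence not the
default.

**Non-identifiability of symmetric rules under contamination.** When an
EQUIVALENT relation is planted with contamination rate $\varepsilon$ drawn
from the same state distribution that forms the margins, the expected
error-mass-to-scope ratio of EQUIVALENT and of each of its constituent
asymmetric rules is *exactly* $\varepsilon \times c$ with the same $c$:
their expected precisions tie. At $\varepsilon = 0$ the sample precisions
tie exactly too and the scope tie-break correctly prefers the symmetric
rule; at $\varepsilon > 0$ sampling noise breaks the tie in either
direction, so the selected template alternates between the symmetric rule
and a constituent. This is a property of the scoring, not a bug: the data
genuinely support both descriptions at equal precision, and the package
reports whichever the sample favors. The suite's recovery experiment
(100 replicates per template at $\varepsilon = 0.05$, $n = 200$) makes the
consequence measurable: asymmetric templates are recovered essentially
always, symmetric ones in roughly a third of replicates, and the pair in
question still receives an edge — just sometimes under the constituent's
name. A tolerance-based tie region cannot fix this without breaking the
exact behavior on small tables, so we kept the literal rule.

**Induction.** All ordered pairs are evaluated blockwise with dense
indicator-matrix products (9 joint-cell products per state pair), giving
the stated O(n²) cost; 2,000 genes × 200 samples complete in well under a
minute on one CPU (timed by the suite and the acceptance script with a
600 s ceiling). Samples missing in either gene are dropped pairwise;
single-state genes are skipped and counted; symmetric rules are emitted
once per unordered pair in lexicographic direction; output ordering is
deterministic, and the TSV writer prints 6 significant digits.

## 3. Baseline methods

The printed comparison methods are implemented at face value: Pearson
correlation (via `stats::cor`) with absolute-value thresholding for
relevance networks; plug-in Shannon entropy and mutual information in
bits without bias correction (maximum-likelihood frequencies; a
correction hook is left to the user, since the plug-in form is what the
comparison used); the one-step StepMiner fit (exhaustive SSE split search
on sorted values, threshold at the midpoint of the two level means, SSE
ties resolved toward the most balanced split) with a `t ± 0.5`
intermediate zone that presumes log2-scale data; and the quadrant
sparsity test `statistic = (expected − observed)/sqrt(expected)`,
`error rate = (observed/row margin + observed/column margin)/2`, sparse
iff statistic > 3.0 and error rate < 0.1 (both strict). The equations are
typeset ambiguously in the source; the implemented reading is fixed by
the margin identities (`n_Ahigh = aI + aIV`, `n_Blow = aIII + aIV`) and
reproduces the worked example (counts 40/15/40/1 give statistic ≈ 3.95,
error rate ≈ 0.024). Sparse quadrants map to rules by the contrapositive
pattern of the worked quadrant-IV case; sparse II∧IV give "equivalent",
sparse I∧III "opposite", replacing their constituents. The discrete-BBN
evaluator implements only the chain-rule joint probability of a full
assignment over a user-supplied DAG with CPTs (structure learning is out
of scope); CPT rows must sum to 1 within 1e-9.

## 4. Centralities, hubs, permutation test

* Degree (total/in/out, normalized by $N-1$), eigenvector, closeness,
  betweenness, VoteRank.
* **Eigenvector** centrality runs on the undirected projection by default:
  implication networks are rarely strongly connected, and the principal
  eigenvector of a non-strongly-connected directed adjacency can be
  degenerate. A directed variant is available. Values are L2-normalized.
* **Closeness** uses the Wasserman–Faust component scaling
  $\frac{r-1}{N-1}\cdot\frac{r-1}{\sum d}$ so disconnected graphs are
  handled without infinities; isolated nodes score 0.
* **Betweenness** is Brandes accumulation (igraph) with endpoints
  excluded; normalization $2/((N-1)(N-2))$ undirected.
* **VoteRank**: abilities start at 1; each round the node with the largest
  neighbor-ability sum is elected, its vote sum recorded as its score, its
  ability zeroed, and neighbors' abilities reduced by $1/\langle k\rangle$
  (floored at 0). Electing with recorded vote sums (unelected nodes
  score 0) gives every node a value so that a full score distribution
  exists; the original scoring convention is not documented.
* **Hubs** are nodes at or above the nearest-rank $(100-p)$th percentile
  cutoff, ties included (default top 10th percentile).
* The **subnetwork permutation test** compares a gene set's mean
  centrality with `n_perm` same-size draws without replacement; the p
  value is the fraction of draws with mean **≥** observed — ties favor
  the null, no +1 smoothing, matching the "fraction of random sets
  ranking higher" reading. Raw values are averaged (a rank-based variant
  is a documented alternative the package does not implement). Results
  are bit-reproducible given `(seed, n_perm)`.

## 5. Gene-set validation

An edge is TP if its genes co-occur in at least one set of any supplied
collection, ND if either gene is missing from the union universe of all
collections, FP otherwise; precision is TP/(TP+FP) over confirmatory
edges only. "Annotated" is evaluated against the union of all collections
because the per-database phrasing of ND is ambiguous; the union is the
more conservative reading (fewer edges dismissed as ND). The permutation
FDR reshuffles class labels, re-derives the network through a
user-supplied derivation callback (the published derivation lives in
prior work and is injected, not reimplemented), and averages FP/(TP+FP)
over permutations that produce at least one confirmatory edge;
permutations producing none are counted and reported, and if every
permutation is empty the FDR is reported as `NA` rather than an invented
0 — the mean has no support. The p value is the fraction of permutations
whose precision reaches the observed one (empty permutations rank below
any defined precision).

## 6. Synthetic data: what it emulates and what it does not

All generators are pure functions of their parameters and a seed.

* `sim_null_states()`: iid states at 15% down / 70% normal / 15% up —
  the marginal distribution implied by the 30% outside-normal
  categorization target, and the null for the calibration experiments.
* `sim_planted_implications()`: the target satisfies the planted
  template's consequent with probability $1-\varepsilon$ wherever the
  source state constrains it and is null otherwise. Defaults used by the
  recovery experiments — $n = 200$ samples, $\varepsilon = 0.05$ — are
  the study conditions for rule recovery; 200 samples is a realistic
  cohort size for the expression datasets this method targets.
* `sim_expression_with_housekeeping()`: Gaussian genes with uniform
  means in [4, 12] and SDs in [0.5, 2] on the log2 scale; housekeeping
  genes share a small SD (0.5). This exercises the calibration exactly,
  but real expression is heavier-tailed and the housekeeping panel is
  never perfectly stable.
* `sim_single_cell_counts()`: zero-inflated Poisson with dropout 0.8 and
  expressed-component mean 2 — the zero fraction matches the dropout
  parameter by construction. Real single-cell data add library-size
  variation, gene-wise dispersion, and expression-dependent dropout that
  this generator deliberately omits; it validates the binarization and
  induction plumbing, not a realistic scRNA-seq profile (splatter-class
  simulation is a non-goal).

Consequently, passing tests demonstrate correctness of the algorithms
under their stated models, and calibration of the statistics under
independence — not performance on real cohorts, which depends on
correlation structure, batch effects and annotation quality that the
generators do not model.

## 7. Numerical choices and problem sizes

Quantiles interpolate linearly (type 7); SDs use the n−1 denominator;
entropies are in bits with $0\log 0 = 0$; boundary states map to normal;
z denominators are floored at machine epsilon and a scope of 1 yields
z = 0 (no discriminating power); all tie-breaks are lexicographic or by
fixed template order so outputs are byte-identical across runs. The test
suite sizes its experiments to the study conditions it checks: 1,000
random tables for the precision identity, 2,000 null pairs and 600
planted replicates at $n = 200$ for calibration and recovery, all
connected graphs on up to 6 nodes (via the graph atlas) plus 50 random
graphs for the centrality oracles, 200 repetitions for permutation-p
uniformity, and one 2,000 × 200 induction for the runtime contract.

## 8. Known limitations

* Symmetric implication rules are not identifiable from their
  constituents at equal sample precision (Section 2); downstream counts
  of EQUIVALENT/OPPOSITE edges should be read with that in mind.
* The binomial z test is conservative; at stringent presets the network
  is sparser than the nominal level suggests. Users wanting tighter
  calibration can lower `z_preset`, at the cost of false positives.
* Housekeeping calibration assumes the panel is representative of the
  genome's within-gene variability up to a scale factor; a panel whose
  variability is atypical shifts every gene's thresholds.
* The MTX reader materializes a dense matrix; very large single-cell
  matrices should be filtered upstream.
* Mixed binary/ternary pairs are supported at the statistic level, but
  `induce_network()` requires one arity per matrix; cross-omics networks
  mixing arities are built by categorizing each layer and joining edge
  lists.
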