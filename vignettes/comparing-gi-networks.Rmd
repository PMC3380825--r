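---
title: "Comparing, error-modeling and combining genetic interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing, error-modeling and combining genetic interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gicompare)
```

## The problem

Quantitative genetic interaction (GI) screens assign every tested gene
pair a signed score: negative (aggravating, down to synthetic lethal)
when the double mutant is worse than expected from the single mutants,
positive (alleviating) when it is better. Screens differ in their
phenotypic readout (colony growth, reporter assays), environmental
condition (e.g. a DNA-damaging agent) and laboratory of origin. Two such
networks never agree perfectly — but how much disagreement should we
*expect* from measurement error alone, and is the remainder genuinely
complementary biology worth combining?

`gicompare` implements the full analysis chain for this question:

1. **Comparison measures** between two networks on their commonly tested
   pairs.
2. An **error model** of the overlap expected from per-sign sensitivity
   and precision, with observed/expected ratios.
3. **Profile similarity networks** and their maximum-correlation
   combination.
4. A **guilt-by-association benchmark**: cross-validated gene function
   prediction per GO term, with relative-improvement statistics.
5. **All-versus-all clustering** of datasets to expose readout,
   condition and laboratory effects.
6. A **synthetic screen generator** with known ground truth so that
   every stage is testable without external data.

## Comparison measures

Networks are undirected; reciprocal query/array measurements are
collapsed onto canonical pairs (mean score by default; the collapse rule
is configurable because published screens do not state theirs). All
comparisons are restricted to pairs tested in every dataset involved, so
an absent call means "tested, nothing detected", not "untested". For two
networks A, B with binarized interaction sets $I_A$, $I_B$ (per sign
class, or combined):

* **correlation** — Spearman's $\rho$ of the quantitative scores over
  all commonly tested pairs (including no-call pairs; an
  interactions-only variant is available as a sensitivity switch),
* **overlap** — Jaccard similarity $|I_A \cap I_B| / |I_A \cup I_B|$,
* **unique** — $1 - \mathrm{overlap}$, the fraction observed in only one
  network,
* **disagree** — among pairs called in both, the fraction whose signs
  differ.

Undefined values (no common interactions, degenerate rank vectors)
propagate as `NA`, never as 0. Positive and negative interactions are
analyzed separately throughout because their error rates differ.
Group-level contrasts (e.g. different-condition networks versus
same-condition controls) use Student's equal-variance t-test, with a
Wilcoxon variant, paired or unpaired.

## The expected-overlap error model

Let $N$ be the number of commonly tested pairs and $n_A$, $n_B$ the
observed interaction counts of one sign class, with sensitivity $s$ and
precision $p$ for that class. Of $n$ reported interactions, $np$ are
true, and those are the fraction $s$ of all true interactions, so each
dataset implies a truth size $T = np/s$; we average the two inversions.
The generative model assumes one shared true set of size $T$ and
conditionally independent errors: dataset $X$ detects each true pair
with effective sensitivity $s_X = n_X p / T$ and falsely calls each null
pair with rate $f_X = n_X(1-p)/(N-T)$. Then

$$E[\mathrm{both}] = T s_A s_B + (N-T) f_A f_B,$$

with the analogous expressions for "only A", "only B" and "neither"
(they sum to $N$), and the expected Jaccard overlap is the ratio of
expectations $E[\mathrm{both}]/E[\mathrm{union}]$ — not the expectation
of the ratio; a Monte-Carlo oracle (`monte_carlo_expected()`) quantifies
the small difference and the test suite requires agreement within three
simulation standard errors. The default rates are the published per-sign
estimates for the reference growth screen (positive $s=0.18$, $p=0.59$;
negative $s=0.35$, $p=0.63$), applied to all datasets because
dataset-specific estimates do not exist.

The interpretive key is the ratio observed/expected: $\approx 1$ for two
error-prone observations of the same biology, $<1$ when conditions
genuinely rewire interactions, $>1$ when shared artifacts (laboratory
batch effects) inflate agreement. Because the literature prints the
ratio in both orientations, the output table reports both.

## Profile networks, combination, function prediction

A gene's interaction profile is its score vector against all tested
partners. For each gene pair the package computes Spearman's $\rho$ over
partners tested with both genes (the pair members are excluded from each
other's profiles by default; a switch includes their mutual score as one
aligned point), and keeps edges with $\rho$ strictly greater than
$\tau = 0.1$ and at least `min_shared = 3` shared partners. Networks are
combined by taking, for every gene pair, the **maximum** correlation
across input networks — deliberately simple, monotone and idempotent;
per-network weight optimization is out of scope.

Function prediction uses Gaussian-field label propagation on the profile
network: solve $(I + L)f = y$ with $L$ the symmetric-normalized
Laplacian of the nonnegative edge weights, $y=+1$ on positives, $-1$ on
negatives and the bias $k=(n^+-n^-)/(n^++n^-)$ on unlabeled genes. GO
annotations come from GAF 2.x files filtered to experimentally supported
evidence codes (EXP, IDA, IPI, IMP, IGI, IEP); terms need at least five
annotated genes in the network. Five-fold cross-validation deals the
shuffled positives round-robin into folds and scores held-out positives
against all non-annotated genes by AUROC (rank-based, ties half) and
AUPR (average precision, descending scores, ties broken by stable gene
id).

Two deliberate choices here deserve explanation:

* **Negatives are not clamped during cross-validation.** The propagation
  operation supports clamping negatives to $-1$, but if evaluation
  negatives are clamped while held-out positives sit at the unlabeled
  bias $k > -1$, every unlabeled gene outranks every negative regardless
  of the graph — a structureless network then scores AUROC $\approx
  0.87$ instead of $0.5$ (we measured exactly this). Cross-validation
  therefore propagates with training positives clamped to $+1$ and
  negatives left at the bias (they still define $k$), which restores
  chance-level behavior on random graphs and makes the benchmark honest.
* **Per-term p-values use a paired t-test across folds.** An exact
  Wilcoxon on five paired fold scores cannot go below $p = 0.0625$, so
  Benjamini–Hochberg selection at 0.05 would be vacuous; the global
  across-terms test remains the paired Wilcoxon signed-rank.

The relative improvement of a combined network $C$ over its parents $A$,
$B$ is $(S_C - \bar S_{AB}) / \bar S_{AB}$ with
$\bar S_{AB} = (S_A + S_B)/2$, reported per term together with the
summary layout (number of terms, improved, worsened, mean, p-value).

## Clustering datasets

All-versus-all matrices of each comparison measure (plus the mean
per-gene profile correlation between dataset pairs) are clustered
hierarchically. Similarity measures are converted to distances as
$d = \max(v) - v$; unique/disagree are dissimilarities already. Ward
("ward.D2"), complete, average (default) and median (WPGMC) linkages are
exposed; merge-height inversions — possible for median linkage only —
are flagged. Rows are ordered by dataset id before clustering so ties
break deterministically. Dendrograms serialize to Newick with branch
lengths equal to merge-height differences (leaves at height 0), so two
leaves merged at height $h$ give `(A:h,B:h);`.

## The synthetic world

The generator exists so that every claim above is testable with known
truth. It has two layers.

**Truth.** Genes partition into modules (default: 300 genes, 10 modules
of 30). Within-module pairs interact with probability 0.8 (negative) and
0.05 (positive). Each module is additionally connected to 3 partner
modules by coherent blocks in which every pair interacts with the same
probabilities; remaining between-module pairs use a sparse background
(0.02/0.01). True $|$score$|$ is $N(4, 1.5)$ floored at 0.1, in S-score
like units.

Block coherence is not optional decoration. Spearman profile correlation
between two genes over $n$-gene profiles scales as roughly
$k/n$ where $k$ is the number of shared strong partners; clearing the
$\tau = 0.1$ threshold at $n = 300$ needs $k \gtrsim 30$. With
independently drawn pairs two same-module genes share
$\sum_k P(g\!-\!k)P(h\!-\!k) \lesssim 2$ partners — profile similarity
can then never carry signal, and guilt-by-association would be untestable
by construction. Coherent blocks are also the biological premise of the
whole approach: genes of one pathway interact with *similar sets* of
genes. The density defaults follow a degree-preservation argument: a
desk-scale 300-gene world emulates the per-gene partner counts of
genome-scale screens (tens of partners per gene), not their per-pair
density, because profile methods operate on partner counts.

**Observation.** Each dataset tests a `coverage` fraction of pairs,
optionally rewires a fraction $\rho$ of its true interactions onto null
pairs (condition-specific biology; counts per sign conserved), detects
each true interaction with the per-sign sensitivity, and adds false
positives on null pairs so the expected per-sign precision equals the
stated precision ($E[\mathrm{FP}] = E[\mathrm{TP}](1-p)/p$) — precision
is targeted rather than a fixed FP rate because that is how screen error
is reported. A fraction `batch_fp_share` of false-positive positions is
drawn from a pseudo-random pool keyed by the laboratory `batch_id`, so
same-lab datasets share artifacts; the batch effect touches false
positives only (the simplest mechanism that makes same-lab networks
"more similar than expected"). Detected scores are the true score plus
$N(0, \sigma)$ noise with the sign forced to match the call (so the
call/score-sign invariant survives noise); false positives draw a fresh
magnitude; undetected tested pairs get call 0 and pure noise. Two
datasets with $\rho = 0$ and no shared batch have conditionally
independent errors given truth — exactly the assumption of the analytic
error model, which is what makes the parameter-recovery test meaningful.

The complementary-signal split used in the combination benchmark is
**gene-anchored**: each module's genes are halved and a true pair goes to
the dataset of its members' halves (coin flip when mixed). Each dataset
carries roughly half of each module's pairs but, crucially, complete
profiles for its half of the genes. An i.i.d. split of pairs would thin
both datasets' partner sets at once (shared partners drop by the square
of the split fraction) and leave profile similarity below $\tau$ in both
halves — no method could then demonstrate complementarity. Under the
gene-anchored split with a clean observation model (sensitivity and
precision 0.9, noise 0.5 — the paper-grade growth-screen sensitivity of
0.35 leaves no profile signal at this scale), the expected shared
detected partner count for same-half module mates is
$\approx 38$ of 298, i.e. $\rho \approx 0.13 > \tau$, while cross-half
mates stay below threshold; the combined network connects both halves.

**What a green test does and does not establish.** The generator
reproduces the statistical structure the analysis assumes — modular
truth, per-sign detection error, condition rewiring, batch-shared
artifacts — not growth-phenotype biology (no fitness model, no
multiplicative expectation), no gene-selection bias across datasets, no
dataset-specific error rates, and no realistic GO term overlap (one term
per module, disjoint). Passing tests establish that the *methods*
recover planted effects of realistic size, not that any particular
biological conclusion is correct.

## Numerical choices and degenerate inputs

* Scores are written with `%.17g`, so edge-list round trips are exact.
* The linear system $(I+L)f = y$ is solved directly (sparse Cholesky via
  Matrix); graphs here are far below the size where iterative solvers
  pay off. Isolated genes receive exactly their prior.
* `estimate_truth_size` errors when the implied $T \ge N$ (rates
  inconsistent with the counts); effective sensitivities are capped at 1.
* Binarization thresholds default to score $\le -2.5$ / $\ge 2.0$
  (conventional S-score cut-offs); calls present in input files take
  precedence over re-binarization.
* Degenerate statistics (zero-variance groups, empty classes, no common
  interactions) return flagged `NA` or exact null results (t = 0, p = 1
  for identical groups), never silent zeros.
* Configuration files are JSON; no YAML parser is available in the
  supported dependency set.
* All randomness flows through explicit seeds; per-dataset seeds derive
  from the dataset id and suite seed via a 31-bit string hash, and batch
  pools from the batch id and suite seed, so study suites are
  byte-reproducible.

## Known limitations

* Error rates are global per sign, not per dataset — matching the
  published practice, but a limitation inherited from it.
* `combine_max` ignores how many networks support an edge; weighted
  multi-network combination is explicitly out of scope.
* The GO machinery does not propagate annotations along the ontology
  hierarchy (off by default, switchable in principle); terms are treated
  as flat gene sets.
* Median-linkage dendrograms may contain height inversions (inherent to
  WPGMC); they are flagged, not repaired.
* The label propagation stands in for an external prediction tool used
  in the original analyses; the benchmark surface is therefore
  property-based (ranking behavior, oracle equivalence), not numeric
  parity with that tool.
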