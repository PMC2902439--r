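---
title: "Comparative eigensystem analysis of cis-regulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative eigensystem analysis of cis-regulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigencis)
```

## The problem

Brain insults such as stroke and prolonged seizures trigger several
concurrent biological programmes — inflammation, apoptosis, altered
synaptic activity — whose transcriptional footprints overlap in any
single expression profile.  `eigencis` implements a comparative strategy
for separating those programmes and dissecting their cis-regulation:

1. each system's ANOVA-filtered log2 expression matrix (genes x
   conditions) is decomposed by SVD into *eigensystems* — triples of an
   eigenarray (unit-norm gene-loading vector), a singular value, and an
   eigengene (unit-norm condition pattern);
2. eigensystems *conserved* between the two systems are identified by
   correlating eigenarrays over the common genes, with a t-based
   p-value;
3. within each conserved eigensystem, gene regulation is modelled by an
   exact Bayesian parent-set search over composite cis-regulatory
   motifs, scored with the Bayesian-Dirichlet equivalence (BDe)
   criterion, with permutation q-values and cross-system validation;
4. the dose dependence of loadings on motif and CNS counts is
   quantified by grouped weighted least-squares regression and a small
   path analysis.

A synthetic-data generator with planted ground truth stands in for the
original microarray and genome-alignment inputs, so every stage is
testable end to end.

## Preprocessing model

Probeset-level MAS5-style signal tables are reduced to gene-level
matrices in a fixed order: (i) keep probesets detected (call `P` or `M`)
on *all* arrays of at least one condition; (ii) average probesets of a
gene on the **linear** signal scale; (iii) log2-transform (signals at or
below zero are floored at `2^-10`, with the floored count reported);
(iv) per-gene one-way fixed-effects ANOVA across all conditions on the
replicate-level log2 values, keeping genes with p below `alpha`
(default 0.05; `alpha = 1` is the keep-everything robustness path), then
average replicates per condition.  Averaging before the log transform is
deliberate: the gene signal is the mean hybridisation intensity of its
probesets, and the log of the mean — not the mean of logs — is what a
single hypothetical probe would have reported.  The per-gene F
statistics are computed by vectorised group-sum algebra and are
cross-checked against `stats::oneway.test` in the test suite.

## SVD conventions

The decomposition is of the *uncentred* log2 matrix, so the first
eigensystem captures the average expression level (its eigengene is
approximately constant in time) and response programmes appear from the
second eigensystem on.  SVD signs are arbitrary; each eigensystem is
oriented so that the eigengene entry of largest magnitude is positive
(ties broken by the earliest condition).  Loadings are raw entries of
`U`, not scaled by the singular value: scale cancels in correlations and
in the sign, which is all that downstream stages consume.

Matching between two systems correlates each pair of eigenarrays
restricted to the common genes and pairs them greedily on `|r|`
descending — the conserved structure this package targets is dominant
and one-to-one, and greedy matching is transparent.  A negative `r` sets
a `sign_flip` flag; consumers negate system-B loadings for that
eigensystem.  The two-sided p-value uses `t = r * sqrt(d / (1 - r^2))`
with `d = n - 2` degrees of freedom and is evaluated in log space, so
magnitudes far below the double-precision underflow limit (powers of ten
near -200 and beyond) remain meaningful; the reported `exponent` is
`floor(log10 p)`.

## The composite-motif model

Putative regulatory regions are conserved non-coding sequences (CNSs):
aligned windows of at least 100 bp with at least 75% identity (both
bounds inclusive, both species tracks required).  A motif family is
*conserved* in a CNS when both species tracks contain at least one
instance, aligned position irrelevant.  A *composite motif* is a set of
one to three families co-occurring in the same CNS — the CNS, not the
gene, is the unit of co-occurrence, so a gene whose CNSs hold {A,B} and
{B,C} carries composites A_B and B_C but not A_C.  Gene-level presence
is the union over the gene's CNSs, which makes presence downward-closed
(a pair implies both singles).  Motif counts per gene sum conserved
instances on a designated count-species track (default rat) over the
gene's valid CNSs; conservation is established first, and only conserved
families are counted.  Composites carried by fewer than
`min_gene_support` genes (default 5) are dropped from the network
feature universe to avoid degenerate contingency tables.

## Bayesian-network scoring and search

The network has a fixed shape: every edge points from a composite-motif
feature to a single binary expression node, the sign of the gene's
loading on one conserved eigensystem (exact zeros are excluded and
counted).  Acyclicity is therefore trivial and the search over parent
sets can be exact.

The marginal likelihood of a parent set is the BDe score with BDeu
pseudocounts: with `q = 2^k` parent configurations and an equivalent
sample size `ess` (default 1), each cell receives pseudocount
`ess / (2q)`.  The structure prior multiplies a penalty `kappa^size`
(default `kappa = 0.5`) per parent, where `size` is the composite's
family count, so larger composites pay more — a guard against
overfitting.  The BN score of a set is the ratio of its posterior to the
empty set's posterior; conditional probability tables report the
posterior-mean probability of a positive sign per parent configuration.

The search runs in two steps: step 1 scores every composite as a
singleton parent and keeps the top `step1_pool_size`; step 2
exhaustively scores every subset of the pool up to `max_parents = 3`.
With the pool sizes used here the subset family is small enough that
exhaustive enumeration is exact by construction.  For the cross-system
design, the two systems' step-1 selections are united and that union is
the step-2 pool on both sides, which makes scores comparable across
systems.

### Permutation q-values

Each feature's q-value is the fraction of permutation-optimal scores at
least as large as its own.  Crucially, each of the `n_permutations`
label permutations reruns the **full two-step search** — step-1
selection included — and records the best non-empty score.  Rerunning
only step 2 on the observed pool would be badly anti-conservative,
because the observed optimum benefits from having chosen its pool on the
observed labels; with the full rerun the observed and permuted optima
are exchangeable under the null, and the probability that an effect-free
dataset yields any q below 0.05 is close to 0.05 (the suite checks this
over 200 effect-free datasets).  When the observed search uses a union
pool, the per-permutation pool is augmented with the *other* system's
observed step-1 selection — a fixed, label-independent set — preserving
exchangeability.  Both the observed statistic and the null use the best
non-empty set, matching the reported (non-empty) features.  Permutation
`i` is seeded with `seed + i`, so nulls are reproducible.

Cross-system validation takes up to `top_features_for_test` training
features with q below the threshold, scores each on the test system, and
assigns test q-values from the **test system's own** permutation null; a
feature is cross-validated when both q-values pass.  Because a single
feature's test score is compared against a null of search *optima*, test
q-values are conservative for null features — a deliberate asymmetry
that favours specificity.

## Count regressions

Single-gene loadings are far from normal, so inference runs on *group
means*: one group per exact integer count (no binning), response = group
mean loading, weights = group sizes, fitted with `stats::lm`.  With
size weights the grouped fit reproduces the gene-level ordinary
least-squares estimates exactly (a unit test asserts this), while the
group level keeps residual diagnostics meaningful.  Eligibility follows
the regressor: motif-count regressions use only genes with at least one
CNS; CNS-count regressions include zero-CNS genes.  Heteroskedasticity
is assessed with the Goldfeld-Quandt test (`lmtest::gqtest`), ordering
by the regressor and omitting the middle third; residual normality with
Shapiro-Wilk on `sqrt(weight) * residual`, reported but never used as a
gate.  The path analysis fits five grouped weighted regressions — three
univariate edges (loading~CNS over all genes, loading~motif over CNS>=1
genes, motif~CNS over CNS>=1 genes) and one bivariate fit giving the two
partial edges — mirroring the question of whether a CNS-count effect is
direct or mediated by the CNSs' motif content.

## The synthetic generator

`synth_config()` defaults describe the study regime the pipeline
expects: system A with 5 conditions and system B with 10, three
replicates per condition, 3000 and 3300 genes with 30% of the smaller
system shared, three dominant shared eigensystems, and replicate noise
of 0.2 log2 units (the arrays' true noise level is not published; this
default is exposed in the configuration).  Expression is built as
`U diag(s) V' + noise`: per-gene baselines (drawn around 8 log2 units)
form a constant row offset whose normalised profile is the shared
magnitude eigensystem; the remaining planted eigenarrays are shared
across systems (identical loadings for shared genes) while the
eigengenes are system-specific orthonormal patterns — conservation of
eigenarrays despite distinct eigengenes, which is exactly what the
matching stage is meant to detect.  With zero noise the construction is
exactly orthonormal and SVD recovers the planted singular values to
machine precision.

Planted cis-regulatory effects act on the eigenarrays *before*
expression synthesis, so SVD re-estimation noise propagates honestly
into every downstream check:

* **Sign effects.**  Carriers of a composite have their loading sign on
  the target eigensystem resampled to positive with probability
  `odds / (1 + odds)`; magnitudes are kept.  An antagonist pair makes
  the blocker dominant: every blocker carrier gets the inverse odds, so
  the effect motif's bias vanishes in the blocker stratum and the
  blocker itself represses — giving both the conditional-probability
  pattern (positive sign likely for effect-without-blocker, unlikely
  for blocker-without-effect) and a flat effect-count slope inside the
  blocker stratum.
* **Count effects.**  The target eigenarray is built as
  `e + sqrt(1 - ||e||^2) * z` where `e = beta * (count - mean)` and `z`
  is unit Gaussian noise orthogonalised against both the previous
  components and `e`.  The column has unit norm and its gene-level
  regression slope on the count is `beta` *exactly*, so "recovered
  within 2 SE of the planted slope" tests the estimation chain rather
  than the generator's own sampling error.  The construction requires
  `beta^2 * sum((count - mean)^2) < 0.9`; the default `beta = 0.012`
  respects that budget at the default scale (a single motif family
  explaining most of an eigenarray would be implausible anyway), while
  recovery tests use `beta = 0.02` at 2000 genes, where the budget
  allows it.

CNS and motif tables are emitted in BED conventions (0-based,
half-open), two species rows per CNS, with lengths of 100 + Exp(90) bp
and identities uniform on [0.75, 0.99]; conserved instances appear on
both tracks, and decoy instances (default 20% of the conserved count)
appear on a single track for families absent from the CNS, so they can
never fake conservation.  What the generator does **not** emulate:
temporally smooth eigengenes (patterns are seeded orthonormal draws),
probe-level sequence effects, cross-hybridisation, correlated noise
between genes, motif positional clustering, or real genome coordinates.
Passing tests therefore demonstrate the correctness of the estimation
machinery under the stated statistical regime, not performance on real
arrays.

## Numerical and scale choices

* Extreme correlation p-values are computed in log space
  (`pt(..., log.p = TRUE)`); `|r| = 1` is reported as p = 0 with a
  degeneracy flag rather than an error.
* Genes with zero within-group variance but unequal means get p = 0
  with a warning flag; completely flat genes get p = 1.
* Step-1 ties (identical presence columns give identical scores) break
  lexicographically on the composite id, and the C++ permutation search
  uses the same ordering, so observed and null searches are consistent.
* The exhaustive step-2 search refuses pools yielding more than 1e7
  subsets and asks for a smaller pool instead.
* Problem sizes in the test suite: generative checks run at 2000 genes
  with `step1_pool_size` 10-15 and 200 permutations; the null
  calibration uses 200 effect-free datasets.  These sizes keep the
  suite's Monte-Carlo error well inside the asserted bands; the
  calibration result is invariant to pool size by the exchangeability
  argument above.
* Singleton count groups keep weight 1 with an undefined (NA) standard
  deviation; collinear bivariate regressors raise a rank-deficiency
  error naming the offending term.

## Known limitations

* Greedy eigenarray matching is not an optimal assignment; it is
  adequate when conservation is dominant and one-to-one, which both the
  target data regime and the generator guarantee, but could mis-pair
  systems with near-tied cross-correlations.
* The BDeu `ess` and penalty base `kappa` are genuinely free
  parameters; defaults (1 and 0.5) are conventional, exposed in
  `bde_config()`, and echoed in run metadata.  With `kappa = 0.5` the
  top-ranked parent set frequently carries a redundant correlated
  sub-composite alongside a true feature; the ranking of the true
  feature itself and its q-value are robust to this.
* The permutation scheme permutes gene labels, assuming exchangeable
  genes under the null; gene-gene correlation in real data would make
  the q-values optimistic there.
* Motif counts require conservation first (instances on the count track
  of CNSs whose other track lacks the family are ignored); the source
  methodology is ambiguous on this point and the stricter reading is
  implemented.
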