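---
title: "Predicting T-cell reactivity from peptide sequence: models and methods"
author: "tcreact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting T-cell reactivity from peptide sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcreact)
```

## The problem

A peptide presented by an MHC class I molecule (for 9-mers, typically on
HLA-A2) triggers an immune response only if a T-cell receptor (TCR)
recognizes the peptide-MHC complex. Binding to the MHC is necessary but not
sufficient: T-cell reactivity — and hence immunogenicity — depends on the
peptide sequence in ways that position-blind descriptors cannot capture.
`tcreact` classifies fixed-length peptides (length 9 by default) as
immunogenic (+1) or non-immunogenic (−1), and provides the statistical
machinery to ask *which positions* of the peptide drive recognition.

## The classifier

### Weighted degree string kernel

Two peptides are compared by counting position-aligned matching substrings.
For sequences $s_i, s_j$ of equal length $L$ and degree $d$:

$$k(s_i, s_j) = \sum_{p=1}^{d} \beta_p \sum_{l=1}^{L-p+1}
  I\!\left(u_{p,l}(s_i) = u_{p,l}(s_j)\right),$$

where $u_{p,l}(s)$ is the length-$p$ substring starting at position $l$ and
$I$ the indicator. The weights are fixed at
$\beta_p = 2(d-p+1)/(d(d+1))$; they decrease with substring length and sum
to one, so for any 9-mer and $d = 9$ the self-kernel is
$\sum_p \beta_p (L-p+1) = 19/3$.

Computationally, each pair is evaluated through the *match-run identity*: a
maximal run of $m$ consecutive positional matches contributes
$\sum_{p \le \min(m,d)} \beta_p (m-p+1)$, giving $O(L)$ per pair instead of
$O(Ld)$; the naive substring enumeration is retained in the test suite as
an independent oracle. Inside cross-validation, per-length match counts are
precomputed once per dataset (an $n \times n \times L$ array), so a grid
over $d$ only reweights that array. Kernel values are used raw; a cosine
normalization switch (`kernelSpec(d, normalize = TRUE)`) exists but is off
by default because the classifier is defined on raw counts.

### Soft-margin SVM on the precomputed Gram matrix

The classifier solves the usual C-SVC dual on the kernel matrix,

$$\min_a \tfrac12 a^\top Q a - e^\top a,\qquad
Q_{ij} = y_i y_j k(x_i, x_j),\quad 0 \le a_i \le C,\quad y^\top a = 0,$$

with an SMO solver (second-order working-set selection) written for
precomputed kernels. The stopping rule is the KKT duality gap; the default
tolerance is $10^{-8}$ for model fits, which makes decision scores
invariant to training-set permutation and antisymmetric under label flips
to well below $10^{-6}$. Cross-validation loops use $10^{-3}$ — the common
working tolerance for model selection — because hyperparameter ranking is
insensitive to the final digits of $a$ while fit time is not. Scores are
$f(q) = \sum_i \alpha_i y_i k(x_i, q) + b$; a peptide is called immunogenic
exactly when $f(q) > 0$, and a score of exactly zero is non-immunogenic.
No probability calibration is applied — raw decision values are the
reported reactivity scores. No class weighting is used: the reference
protocol targets nearly balanced data, and the synthetic generator defaults
to exact balance.

The production configuration (`trainFinalModel`) is $C = 1$, $d = 9$, the
pair that inner cross-validation selects essentially always on data of this
kind.

## Evaluation protocol

Performance is measured by overall accuracy (ACC), Matthews correlation
(MCC) and the area under the ROC curve (AUC):

$$ACC = \frac{TP + TN}{TP+TN+FP+FN},\qquad
MCC = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}.$$

A zero MCC denominator (degenerate confusion matrix) is defined as
MCC = 0, with a logged warning. AUC is estimated as the Mann-Whitney
statistic with half credit for ties; the test suite pins it against both
pairwise enumeration and `pROC`.

`nestedCV` implements nested 10-fold cross-validation: outer folds estimate
generalization; for each outer fold an inner 10-fold CV on the remaining
9/10 selects the $(C, d)$ pair with the highest mean inner AUC from the
grid (defaults $C \in \{2^{-4},\dots,2^4\}$, $d \in \{1,\dots,9\}$); ties
go to the smallest $d$, then the smallest $C$, preferring the simpler
model. The procedure is repeated (reference protocol: 20 runs) and
summarized as across-run means and standard deviations. Folds are
*stratified*: the reference description says only "randomly divided", but
stratification prevents degenerate single-class folds on the modest
synthetic datasets this package is validated on, at no cost otherwise. All
randomness flows from one explicit seed recorded in the report.

`learningCurve` reproduces the sample-size analysis: one stratified
50/25/25 split into training pool, validation and test, then models trained
on increasing subsets (fixed $C = 1$, $d = 9$ by default; passing a grid
enables re-tuning at every size).

### The position-blind baseline

`baselinePropertySVM` is the comparison method: peptides are encoded as
vectors of per-property means over an AAindex-style table (a
position-independent representation), and an RBF-kernel SVM
$k(x,y) = \exp(-\gamma\|x-y\|^2)$ is run through the *same* nested-CV
protocol, tuning $C$ and $\gamma$ over $\{2^{-4},\dots,2^4\}$. Encoding
columns are z-scored (once, label-free) before the kernel; raw AAindex
scales differ by orders of magnitude and would make the fixed $\gamma$
grid meaningless. The contrast between the two models is the scientific
point: on composition-matched data whose labels depend only on *which*
position carries a residue, the mean-property baseline is blind (AUC ≈
0.5) while the string kernel separates the classes.

## Interpretation machinery

### Position-deletion importance

`positionImportance` removes one position at a time
(`deletePosition`), reruns the nested CV on the shortened peptides with the
degree grid capped at the remaining length $L-1$, and reports
$\Delta MCC = MCC_\text{baseline} - MCC_\text{deleted}$ per position;
larger drops mean more important positions. Baseline and deleted runs are
seed-matched so fold noise largely cancels. A position is flagged
"important" when its $\Delta MCC$ exceeds twice the across-run sd of the
deleted-position MCC — the reference description says only "decreased
significantly", so the package states its criterion explicitly.

### Two-sample logos

`twoSampleLogo` compares, for every (position, symbol) cell, the binary
occurrence indicators between the two sets with a two-sample t-test.
Welch's unequal-variance form is the default — binary indicators with
different frequencies have unequal variances by construction — and a
pooled-variance option is provided. Degenerate cells are handled without
error: indicators constant and equal in both sets give $p = 1$; constant
but different give $p = 0$. Significance uses Bonferroni correction with
the family defined as *all* $m = L \times |\mathcal{A}|$ tests (180 for
amino acids, 27 for the S/M/L alphabet); $m$ is recorded in every report
since other family choices would shift marginal calls. The logo plot draws
significant symbols with heights proportional to the frequency difference;
all testing targets the numeric report, never rendered pixels.

### Property-recoded logos

`recodeAlphabet` maps residues to a coarse S/M/L alphabet by thresholding a
per-residue scalar: S below the low threshold, M in [low, high), L at or
above the high one. Two scales ship with the package: hydrophobicity with
thresholds 0.5/2.5, for which the Kyte-Doolittle hydropathy index is used
(the package's choice of concrete scale; the thresholds then class
{C, F, I, L, V} as L and {A, M} as M), and normalized van der Waals volume
with thresholds 2.0/6.0 (glycine, the smallest residue, is class S).
`propertyLogo` chains recoding and the two-sample logo over {S, M, L}.
Conveniently, S, M and L are themselves canonical residue letters, so
recoded datasets remain valid `PeptideSet`s.

### Feature usage from an information-gain tree

`featureUsageRanking` grows a single binary decision tree on the
mean-property encoding by maximal information gain (thresholded features;
stopping at pure nodes, a minimum child size of 5, or zero gain; ties
broken toward the lowest feature index so results are deterministic). The
*usage* of a feature is the percentage of training cases routed through at
least one node testing it — the root feature of a non-trivial tree is
always at 100% — and properties are ranked by usage. This is a transparent
surrogate for proprietary rule-based tree learners whose exact usage
percentages depend on pruning configuration; the ranking construct, not
any specific percentage, is what the package relies on. No pruning is
applied; the minimum-leaf-size parameter guards against overfitting small
fixtures.

### AAindex handling

`readAAindex`/`writeAAindex` parse and emit the AAindex1 flat-file dialect
(H/D/I blocks, two rows of ten values in the canonical A/L ... I/V column
order, `NA` for missing entries). Records with any missing value are
parsed but flagged incomplete and excluded from encodings. The bundled
table (`defaultPropertyTable()`) holds a dozen classical scales
(hydropathy, hydrophilicity, volume, polarity, weight, pI,
secondary-structure propensities) plus clearly marked synthetic records —
one with missing values to exercise the completeness path. It is a compact
stand-in; the full AAindex database can be supplied as an external file
and is never required.

## The synthetic data generator

Because the curated immunogenicity dataset behind the reference protocol
is not redistributable, every pipeline stage is validated on synthetic
peptides with planted, recoverable ground truth (`generateDataset`,
`defaultBenchmarkSuite`):

* **rule** — deterministic single-position rule (+1 iff G at position 4):
  perfectly separable, used for recovery and importance tests;
* **enrichment** — probabilistic position-specific preferences shaped like
  empirically reported immunogenicity logos: G enriched at position 4
  (0.40 in positives vs 0.10 in negatives), V at 6 (0.35/0.10), T at 8
  (0.35/0.10), with T depleted at 6 (0.05/0.25) and I at 9 (0.05/0.25).
  The exact frequencies are the package's choice of a realistic moderate
  effect size — strong enough to recover at n = 200, far from separable;
* **null** — background-only labels for calibration;
* **positionSwap** — every peptide carries {G, L} at positions 4 and 6,
  positives as G4/L6, negatives as L4/G6: identical residue composition,
  purely positional labels. This is the dataset that separates the string
  kernel from the mean-property baseline.

At a motif position the listed residues appear with exactly their
configured class frequency and the remaining mass is spread over the
background restricted to the unlisted residues; listed frequencies summing
above 1 are rejected as contradictory. The default background is uniform
over the 20 canonical residues (a frequency table can be supplied).
Positions are independent given the class. Real epitopes violate both of
these — natural residue abundances are skewed and anchor positions
correlate — so passing recovery tests demonstrates that the *machinery*
recovers planted structure, not that any particular biological claim
holds; conclusions about real immunogenicity data still require real data.

## Numerical and scale choices

* Degenerate inputs: single-class training sets, empty peptide sets,
  ragged lengths, non-canonical residues (B, J, O, U, X, Z, lowercase) and
  out-of-range degrees all raise immediate errors; contradictory duplicate
  annotations in input files are resolved to immunogenic with a logged
  count, matching the curation convention of the reference datasets.
* Solver: duality-gap tolerance $10^{-8}$ (fits) / $10^{-3}$ (CV loops),
  iteration cap $2 \times 10^6$; bias from free support vectors when any
  exist, otherwise the KKT midpoint.
* Model archives are JSON with 17 significant digits, so load-then-predict
  reproduces scores bit-identically.
* The validation protocol in `tests/` and `scripts/acceptance.R` runs at
  deliberate desk scale: datasets of 100–400 peptides, reduced grids
  (e.g. $C \in \{2^{-2}, 1, 2^2\}$, $d \in \{1, 5, 9\}$) and 1–5
  repetitions rather than the full $9 \times 9$ grid with 20 runs. The
  planted effects are strong enough that the reduced protocol decides the
  qualitative questions; the full grid and 20 runs remain the defaults for
  real analyses.
* Parallelism is deliberately absent: every result is a deterministic
  function of (data, parameters, seed). The CLI accepts `--threads` for
  interface stability but executes serially.

## Known limitations

* Only binary labels; graded reactivity would need quantitative response
  data and a regression formulation.
* One model per dataset: peptides presented by different MHC alleles
  should be split into allele-specific datasets upstream.
* The generator's independence assumptions (see above).
* Reported nested-CV numbers on published curated data (mean ACC ≈ 0.68,
  AUC ≈ 0.74 for the string-kernel model vs ACC ≈ 0.60, AUC ≈ 0.64 for the
  mean-property baseline on ~1085 HLA-A2 9-mers) are documentation for
  users who supply such data themselves; nothing in this package's test
  surface depends on them.
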