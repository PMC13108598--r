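---
title: "Supervised MSA column filtering: model, calibration and design notes"
author: "msafilter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised MSA column filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msafilter)
```

## The problem and the model

Multiple sequence alignments of divergent sequences contain columns that are
poorly aligned or carry little signal; removing them ("trimming",
"filtering") is routine before phylogenetic inference. Automated trimmers
apply fixed criteria; human annotators apply judgement, which is accurate
but slow and irreproducible. `msafilter` treats an annotator's column calls
as training labels and learns a logistic surrogate of their judgement.

Each column yields six features (gap proportion; percent identity excluding
gaps; distance in columns to the nearer alignment end; Shannon entropy in
nats excluding gaps; gap proportion averaged over the ±1 and ±2 column
windows, truncated at the alignment edges). With the constant term $f_0=1$,
the preservation score of a column is

$$p = \mathrm{logit}^{-1}\Big(\sum_{i=0}^{6} m_i f_i\Big),\qquad
\mathrm{logit}^{-1}(x)=\frac{1}{1+e^{-x}},$$

and the column is preserved iff $p > t$ (a tie $p = t$ removes it). The
definitions are identical for nucleotide and amino-acid data — only the
entropy ceiling differs ($\ln 4$ vs. $\ln 20$) — so one model can be trained
on, and applied to, either. The alignment-level confidence
$C = 1 - \tfrac{4}{n}\sum_k p_k(1-p_k)$ is 0 when every score sits at 0.5
and approaches 1 as scores saturate; it measures decisiveness, not
correctness, and each column contributes symmetrically in $p_k
\leftrightarrow 1-p_k$.

Modelling assumptions worth stating: columns are scored independently given
their features (the windowed gap features are the only context); the
annotator's style is expressible as a single linear decision boundary in the
six features (styles based on, say, parsimony-informativeness are not in
this feature span); and the training masks are mostly, but not necessarily
perfectly, correct.

## Training, validation, testing

* **Training** pools every column of the training alignments into one
  design matrix and fits $m_0..m_6$ by iteratively reweighted least squares
  on the mean log loss.
* **Validation** first scans $t \in \{0, 0.01, \dots, 1\}$ for the value
  maximizing the chosen metric (MCC by default; accuracy or $F_\beta$ by
  option) on the pooled validation columns, then — with $t$ fixed — searches
  the sequence-bootstrap grids $b \in \{0, 100, \dots, 1000\}$,
  $t_b \in \{0.05, \dots, 0.95\}$. The bootstrap resamples alignment *rows*
  with replacement, recomputes all features per replicate, and preserves a
  column only if at least $t_b \cdot b$ replicates score above $t$. The
  selected $b$ maximizes the regularized score $S = M - bE$ with
  $E = 5\times10^{-5}$, so 100 further replicates must improve the metric by
  at least 0.005.
* **Testing** applies the validated model unchanged to held-out alignments
  and reports confusion counts, MCC, accuracy, $F_\beta$, log loss, $C$, the
  ROC curve and its AUC, pooled and per alignment.

Partitioning (`partitionAlignments()`) always assigns whole alignments to a
single split (largest-remainder rounding of the 2:1:1 ratios, seeded
shuffle): columns of one alignment share structure, so splitting an
alignment across train and test would leak information.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `t` | 0.5 until validated | decision threshold on $p$; 0.5 is the symmetric prior for unvalidated models |
| `b` | 0 until validated | bootstrap replicates; off unless validation shows they pay for themselves |
| `tb` | 0.5 | fraction of replicates that must pass; searched on a 0.05 grid |
| `penalty` (E) | 5e-5 | cost per replicate in $S = M - bE$ |
| `metric` | MCC | balanced correlation; accuracy and $F_\beta$ available for unbalanced preferences |
| `tol` | 1e-8 | IRLS gradient max-norm (standardized scale) |
| `maxIter` | 100 | IRLS iteration cap |
| `mistakes` | 0 | proportion of training flags flipped, for robustness studies |

## Numerical choices

* **Standardization.** Features are z-scored inside `fitLogistic()` for
  conditioning (the distance feature can span hundreds of columns while the
  fractions stay in $[0,1]$); coefficients are back-transformed, and the
  returned predictions match a raw-scale fit to $10^{-10}$.
* **Step-halving.** A Newton step that would increase the loss is halved
  toward the current iterate, so the loss trace is non-increasing by
  construction.
* **Separation.** Perfectly separable training data have no finite optimum;
  the fit refuses with an explanatory error instead of returning runaway
  coefficients or silently adding a ridge penalty.
* **Saturation.** Scores are clamped to $[10^{-12}, 1-10^{-12}]$: $p$ stays
  strictly inside $(0,1)$ and log losses stay finite.
* **Degenerate columns.** All-gap columns take identity 0 and entropy 0;
  their gap proportion of 1 already drives them toward removal. MCC with a
  zero marginal is defined as 0. A filter run that removes every column
  returns a zero-column alignment with a warning rather than an error.
* **Bootstrap rule.** `count >= tb*b` is evaluated with a $10^{-9}$ slack:
  pass counts are integers but `0.7 * 100` is fractionally above 70 in
  floating point, and the rule must read "at least".
* **Ties.** Threshold ties break toward 0.5 then toward the smaller $t$;
  bootstrap ties toward smaller $b$ then smaller $t_b$ (computational
  parsimony). ROC thresholds sit at the unique score values with ties
  grouped; AUC is the rank statistic, which equals the trapezoidal area of
  that curve.
* **Seeding.** Every stochastic operation (partitioning, mistake injection,
  bootstrap, generators) takes an explicit seed and restores the caller's
  RNG state; sub-seeds for per-alignment work are derived from the master
  seed. Computation is serial throughout, so results cannot depend on a
  thread count. With $b=0$ the filter is fully deterministic:
  repeated runs are byte-identical.

## The synthetic-data generator

`generateAlignment()` and `generateCorpus()` produce alignments from block
layouts of three kinds: *conserved* (a consensus residue per column with at
most 10% deviant sequences — percent identity $\ge 0.9$ by construction —
labelled preserve), *variable* (near-uniform residues with moderate gap
content, labelled delete), and *gappy* (per-column gap fraction guaranteed
$\ge 0.85$, labelled delete; the 85% level mirrors the gap pre-filter
customary in manual curation). The default corpus draws 10–30 sequences and
4–10 blocks of 10–40 columns per alignment with kind probabilities
0.45/0.30/0.25, and labels each variable block preserve with probability
0.1 — emulating an annotator deliberately keeping a fast-evolving region.
That last ingredient matters twice: it is the realistic irreducible
disagreement between features and labels, and it keeps the training problem
from being perfectly separable (which the fitter would refuse).

What the generator does **not** emulate: phylogenetic correlation among
sequences, indel evolution, site-rate heterogeneity, alignment-program
artefacts, or annotators whose criteria drift along the alignment. Green
tests on this corpus therefore demonstrate that the machinery learns and
reproduces a feature-expressible filtering style from small labelled
corpora — they do not certify accuracy on any particular biological
dataset, which depends on how well that dataset's annotation style lives in
the six-feature span.

## Problem sizes used in the checks

The test suite works at deliberately modest scale: feature oracles on 100
random 10×20 alignments; metric oracles on 1000 random confusion tables;
coefficient recovery on 20,000 generated columns; and the corpus studies on
31 alignments (14 train / 7 validation / 10 test, a size at which the
full-data behaviour is already reached). The annotation-mistake study flips
0–40% of the training and validation labels (5 seeds per rate) and checks
that clean-test accuracy and MCC stay within 0.05 of the mistake-free model
while $C$ falls monotonically — the mistake experiment calibrates the
threshold only ($b=0$), since the bootstrap search is orthogonal to label
noise and is exercised by the pipeline tests.

```{r example, eval = FALSE}
corpus <- generateCorpus(31, seed = 42)
aln <- lapply(corpus, `[[`, "alignment")
msk <- lapply(corpus, `[[`, "mask")
model <- trainModel(aln[1:14], msk[1:14])
validated <- validateModel(model, aln[15:21], msk[15:21], seed = 7)
testModel(validated, aln[22:31], msk[22:31], seed = 3)$pooled
```

## Design decisions that were genuinely open

* **Gap alphabet.** `-`, `.` and `?` are gaps; everything else, including
  ambiguity codes (X, N, ...), counts as a residue — the conservative
  reading when features are defined purely by the gap/residue dichotomy.
* **Distance from extremity** is counted in alignment columns,
  $\min(i, L-1-i)$, not in residues of any particular sequence: the only
  row-independent reading for a column-level feature.
* **Mask file format** (one line of 0/1 with optional `#` comments) and the
  **model JSON schema** (`format_version`, `coefficients`, `threshold`,
  `bootstrap_replicates`, `bootstrap_threshold`, `validated`, `metadata`)
  are local conventions of this package; no interoperability with other
  tools' model files is claimed. JSON numbers are written with 17
  significant digits so round trips are bit-exact.
* **Mistake injection** flips an exact count, `round(proportion * L)`,
  uniformly without replacement — deterministic given the seed, unlike
  per-column Bernoulli draws.
* **Sequential calibration** ($t$ first, then $(b, t_b)$ with $t$ fixed)
  rather than a joint 3-D search: the two stages answer different questions
  and the joint search would multiply the bootstrap cost by the threshold
  grid. Metric pooling across validation alignments (not per-alignment
  averaging) matches the pooled training objective.
* **Bitwise mask combination** across models offers both intersection and
  union, since either consolidation (strict core) or permissiveness may be
  wanted when comparing filtering styles.

## Known limitations

Only whole columns are filtered — never rows, blocks or realignments. The
logistic boundary cannot express filtering styles driven by features outside
the six (tree-aware rates, parsimony-informativeness). Validation metrics
are pooled over columns, so one very long validation alignment can dominate
the calibration. The bootstrap assumes exchangeable rows, which
phylogenetic structure violates; its replicate counts should be read as
stability indicators, not probabilities.
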