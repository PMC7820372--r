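---
title: "Methods: two-tier sequence-based apolipoprotein classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-tier sequence-based apolipoprotein classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Apolipoproteins are the protein components of plasma lipoproteins; their
subfamilies (ApoA through ApoR) differ in function and disease association.
Annotated apolipoproteins number in the hundreds while tens of thousands of
candidate sequences remain unannotated, so a sequence-only classifier is a
practical triage tool. `apofam` implements a two-tier predictor: tier 1
decides apolipoprotein vs non-apolipoprotein; tier-1 positives proceed to
tier 2, which assigns one of seven subfamily labels (ApoA, ApoB, ApoC,
ApoD, ApoE, ApoL, and `Apoelse`, a pooled class for the small subfamilies
ApoF/H/M/N/R that are individually too rare to model).

## Sequence encoders

Every classifier input is a fixed-length numeric vector computed from the
amino-acid sequence alone. Four encoders are provided; all use the
alphabetical residue ordering `ACDEFGHIKLMNPQRSTVWY`.

**Dipeptide composition (DPC, 400 features).** Component $(r, s)$ is
$N_{rs} / (L - 1)$: the count of the adjacent pair $rs$ over the number of
adjacent pairs in a sequence of length $L$. The vector sums to 1.

**k-spaced amino-acid pairs (CKSAAP, $400(k_{\max}+1)$ features).** For
each spacing $k = 0, \dots, k_{\max}$ (default $k_{\max} = 5$, i.e. up to
five residues between the pair members), the count of ordered pairs $(a,b)$
with $a$ at position $i$ and $b$ at position $i + k + 1$ is divided by the
number of such positions, $N_{\mathrm{total}}(k) = L - (k+1)$. Each
400-feature block therefore sums to 1 and the $k=0$ block equals DPC.

**Composition/transition/distribution (188D).** The 20 residue frequencies,
followed, for each of eight physicochemical groupings that partition the
alphabet into three groups (hydrophobicity, normalized van der Waals
volume, polarity, polarizability, charge, secondary-structure propensity,
solvent accessibility, surface tension), by: the three group frequencies;
the three cross-group adjacent-pair frequencies (unordered, over $L-1$);
and, per group, the positions of its first, 25th-, 50th-, 75th-percentile
and last occurrence divided by $L$ (the percentile point of a group with
$n_g$ occurrences is occurrence number $\lceil q\, n_g \rceil$; an absent
group contributes five zeros). Total: $20 + 8 \times (3 + 3 + 15) = 188$.

**Pseudo-amino-acid composition (PseAAC, $20 + 9\gamma$ features).** Nine
physicochemical properties are used: hydrophobicity, hydrophilicity,
side-chain mass, pK1 ($\alpha$-COOH), pK2 (NH$_3^+$), pI at 25°C,
rigidity, irreplaceability and flexibility. Each property profile
$h_p(\cdot)$ is standardized to zero mean and unit variance over the 20
residues. For tier $j = 1, \dots, \gamma$,

$$\tau_{p,j} = \frac{1}{L-j} \sum_{i=1}^{L-j} h_p(R_i)\, h_p(R_{i+j}),$$

a per-property autocorrelation of the sequence at lag $j$ (the "series"
correlation form, chosen because it yields exactly the $20 + 9\gamma$
dimensionality). With raw residue frequencies $f_u$ and weight $w$
(default 0.05, the conventional choice; $\gamma$ defaults to 10), the
vector is

$$A_u = \frac{f_u}{\sum_v f_v + w \sum_{p,j} \tau_{p,j}}, \qquad
A_{20 + 9(j-1) + p} = \frac{w\, \tau_{p,j}}{\sum_v f_v + w \sum_{p,j} \tau_{p,j}},$$

so the whole vector sums to 1; $\gamma = 0$ reduces to plain composition.

The numeric property table is a versioned built-in compilation
(`apofam-tables-1`): six scales from standard biochemistry references
(hydrophobicity, hydrophilicity, mass, pK1, pK2, pI), the Charton steric
parameter standing in for rigidity, an irreplaceability index derived from
genetic-code degeneracy ($1/\text{codon count}$), and the
Bhaskaran–Ponnuswamy flexibility index. Because the properties enter only
after per-property standardization, results are invariant to each scale's
units; still, other compilations of the same nine property names would give
numerically different PseAAC vectors, which is why the table is versioned
and recorded in every `encoder_config`.

## Feature selection

Features are ranked by the one-way ANOVA F-value,
$F = \mathrm{MS}_{\text{between}} / \mathrm{MS}_{\text{within}}$ with
$k - 1$ and $n - k$ degrees of freedom across the label groups.
Conventions: a feature constant across all samples takes $F = 0$ (0/0); a
feature with zero within-group variance but distinct group means is a
perfect separator and takes $F = \infty$, ranking first. Ties preserve the
original column order.

Incremental feature selection (IFS) then grows the subset along the
ranking, evaluating each size by stratified cross-validated accuracy and
returning the smallest size that attains the maximum (flat curves therefore
select size 1). Two design choices matter:

* **Fold-internal re-ranking.** The accuracy reported for each subset size
  is computed with the ranking recomputed inside each training fold. If
  instead the full-data ranking is reused (available as
  `refold_rank = FALSE`), picking the best few of hundreds of features
  *on the data that also evaluates them* inflates the curve dramatically
  on pure noise, while the fold-internal procedure stays at chance level
  (the test suite demonstrates this gap directly).
  The returned `optimal_features` are still the top-$n$ of the full-data
  ranking, since that is the subset a final model trained on all data uses.
* **Fixed mid-grid hyperparameters inside IFS.** Running a full grid search
  for every subset size would multiply cost for little benefit; the subset
  sweep uses cost 32 and kernel width $1/d$, and the final model's
  hyperparameters are then tuned by grid search on the chosen subset.

## Classifiers

Both tiers are RBF-kernel support-vector machines (libsvm via `e1071`),
with one-vs-one voting for the multiclass tier. Features are standardized
with training-set mean and standard deviation before the kernel (an RBF
kernel on unscaled heterogeneous features is dominated by the
widest-ranging ones); the scaling is stored in the model and re-applied at
prediction. Grid search evaluates stratified CV accuracy over
$C \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}$ and kernel width
$\in \{2^{-15}, 2^{-13}, \dots, 2^{3}\}$ (the SVM's RBF $\gamma$, called
`kernel_width` throughout to avoid collision with the PseAAC tier count),
breaking ties towards smaller cost then smaller width. Default encoders:
PseAAC ($\gamma = 10$) for tier 1 and CKSAAP ($k_{\max} = 3$) for tier 2,
the representations that perform best for identification and subfamily
classification respectively.

## Evaluation

`kfold_cv()` uses stratified folds with a recorded seed and fits the whole
pipeline — encoding, ranking, selection, training — inside each training
fold only. Metrics are pooled (micro-averaged): held-out confusion counts
are totalled first, then sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, accuracy and the Matthews correlation coefficient are
computed once from the totals; when any MCC denominator factor is zero,
MCC is defined as 0. The ROC curve sweeps all distinct decision-score
thresholds (one vertex per distinct score, so ties are grouped) and AUC is
the trapezoidal integral, which equals the normalized Mann–Whitney
statistic with ties counted one half. Multiclass reports give overall
accuracy and per-class sensitivity (class-wise recall), whose count-weighted
mean equals the overall accuracy by construction.

## Benchmark curation

Curation follows the standard recipe for this problem: drop sequences with
non-standard characters (B, J, O, U, X, Z) or fewer than 10 residues, then
reduce redundancy at 80% identity. Rather than re-implementing CD-HIT's
word-filtering heuristics, `reduce_redundancy()` uses transparent greedy
clustering in descending length order (ties by id): a sequence joins the
first retained representative with identity at or above the cutoff, else
becomes a representative. Identity is the number of identical aligned
positions under global alignment (match 1, mismatch 0, linear gap penalty
1) divided by the shorter sequence's length — the CD-HIT convention.
Cluster membership can differ from CD-HIT's in edge cases, but redundancy
filtering only gates the training data and exact membership is not part of
any reported quantity; an externally produced representative list can be
supplied instead.

## The synthetic generator

`generate()` emulates the two signal types the encoders exploit. Each
class draws a residue-frequency profile from a symmetric
Dirichlet($\alpha$) over the 20 residues and emits sequences i.i.d. from
it — this creates the compositional contrast that PseAAC, DPC and 188D
detect, with $\alpha$ (`composition_concentration`, default 5) the single
effect-size knob: small $\alpha$ gives strongly contrasting profiles,
$\alpha \to \infty$ makes classes compositionally identical. On top,
each class owns a few planted $(a, b, k)$ residue pairs (default 3 per
class, spacings 0–3), stamped at each eligible start position
independently with probability `pair_signal_strength` (default 0.08) —
the pair-level contrast that CKSAAP detects. Ground truth (profiles and
planted pairs) is returned with the data. Sequence lengths are uniform on
80–200, within the range of real apolipoproteins and long enough for every
encoder precondition; the default two-tier study uses 7 subfamilies × 30
positives and 200 negatives, sizes at which the full pipeline runs in
seconds on one core.

What the generator does **not** emulate: phylogenetic correlation between
sequences, insertion/deletion structure, domain architecture, position
dependence of composition, or the homology that survives real redundancy
filtering at 80% identity. Tests passing on this data therefore demonstrate
that the pipeline recovers compositional and k-spaced pair signal without
leakage — not that real apolipoproteins are identified at any particular
accuracy. The published benchmark for this problem is distributed only
through its authors' webserver, so the synthetic study is the package's
reproducible reference point.

## Numerical choices and degenerate inputs

* Empty sequences are invalid; encoders require $L \ge 2$, CKSAAP
  $L \ge k_{\max} + 2$, PseAAC $L \ge \gamma + 1$. Violations raise errors
  naming the offending record.
* Constant feature columns get scale 1 during standardization (mapping to
  exact zeros) rather than dividing by zero.
* IFS and grid-search fold assignments are stratified and derived from a
  recorded seed; repeated runs with the same inputs and seed produce
  byte-identical serialized artifacts.
* Grid-search ties go to the smallest cost, then the smallest width;
  IFS accuracy ties go to the smallest subset.

## Limitations

Tier 2 is trained only on apolipoproteins, so its subfamily posterior is
meaningless for sequences tier 1 misclassifies as positive. PseAAC values
depend on the shipped property table; exact agreement with other PseAAC
implementations is not expected. The greedy identity clustering is
quadratic in dataset size and intended for benchmark-scale (hundreds to a
few thousand sequences), not proteome-scale, input.
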