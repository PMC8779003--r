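---
title: "The scoring card method for tumor-homing peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scoring card method for tumor-homing peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmpep)
library(dplyr)
```

## The model

Tumor-homing peptides (THPs) are short peptides — typically 3 to 30
residues — that selectively recognize tumor cells or tumor vasculature,
often through motifs such as RGD and NGR and through disulfide-stabilized
cyclic scaffolds. The scoring card method (SCM) classifies a peptide from
nothing but its amino-acid composition: each of the 20 standard residues
carries a propensity score $APS_i$ on a 0–1000 scale, and a peptide $P$ of
length $L$ receives the weighted-sum score

$$ SF(P) = \sum_{i=1}^{20} aa_i \, APS_i, $$

where $aa_i$ is the occurrence frequency of residue $i$ in $P$ (count over
length, so $SF$ is equivalently the mean propensity over sequence
positions). $P$ is called a THP when $SF(P)$ strictly exceeds a cutoff;
a score exactly at the cutoff is classified negative. The model is fully
interpretable: the card *is* the model, and reading it off ranks residues
by their contribution to tumor-homing activity.

Two consequences of the weighted-sum form are worth keeping in mind and
are asserted as properties in the test suite: the score is invariant to
residue order (SCM sees composition only), and an affine transform of the
card induces the same affine transform of every score, so ranking-based
quantities such as AUC are unchanged.

## Training

Training has three stages.

**Initial scores.** For each residue we take the pooled composition in the
positive class (residue count over total residues) and divide by the
pooled composition in the negative class; the 20 ratios are min–max
rescaled to integers in $[0, 1000]$. A residue absent from a class
receives a pseudo-composition of one count over the class residue total,
keeping the ratio finite with minimal distortion. If the two classes have
identical compositions the ratios are all equal and the card is degenerate;
we flag this with a warning and return a flat card rather than guessing.

**GA refinement.** A genetic algorithm searches for a card maximizing

$$ Fit = W_1 \cdot AUC + W_2 \cdot R, \qquad W_1 = 0.9,\ W_2 = 0.1, $$

where AUC is that of the weighted-sum scorer on the training peptides and
$R$ is the Pearson correlation between the candidate's 20 scores and the
initial card. The correlation term is what preserves interpretability: it
anchors the optimized card to the composition evidence instead of letting
the optimizer drift to an arbitrary weight vector. Because a candidate
card has no fold-fitted parameters, pooling out-of-fold scores across
stratified folds gives exactly the same AUC as scoring the whole training
set at once; we therefore compute the fitness AUC directly on the training
set. Cross-validation proper (refitting the entire procedure per fold) is
available through `cross_validate()` and is what `scm_train(cv = TRUE)`
reports.

The GA encodes a card as 20 integers clamped to $[0, 1000]$ and uses, by
default, a population of 50, 100 generations, tournament selection of size
3, uniform crossover with rate 0.8, per-gene mutation with rate 0.05 and a
uniform step of at most ±100, and elitism of 2. These are conventional
settings in the SCM literature; every one is exposed in `ga_config()`.
The population is seeded with the unperturbed initial card, so with any
elitism the best fitness is non-decreasing and the optimized card can
never be worse than the initial one — both guaranteed by construction and
asserted in the tests. Runs are bit-reproducible given `seed`; repeated
independent runs (`run_experiments()`) use consecutive seeds and are
ranked by cross-validated accuracy, which is how a final model is chosen.

**Cutoff.** The decision threshold is the smallest integer in the span of
the training scores that maximizes training accuracy under the strict-`>`
rule. Searching integers matches the integer scale of the card; taking the
smallest maximizer makes ties deterministic.

## Evaluation

`classification_metrics()` implements accuracy, sensitivity, specificity
and MCC from the confusion counts, with the usual convention that MCC is 0
whenever a denominator factor vanishes. AUC uses the rank (Mann–Whitney)
estimator with midrank ties, which equals the trapezoidal area under the
empirical ROC; the tests verify it against exhaustive pair enumeration and
against pROC. Folds are stratified because the benchmark design is
balanced; assignment is seeded.

One numerical caveat: raw scores are sums of floating-point fractions, so
peptides that are tied in exact arithmetic can differ by a few ulps. This
is irrelevant at the integer reporting scale and for any data with real
signal, but it is why the test suite uses an all-zero card (exactly tied
scores) when exercising the all-ties AUC convention.

## The reference card and worked examples

The package embeds a published optimized THP card
(`scm_reference_card()`, cutoff 301), the 20 highest- and 20
lowest-scoring peptides under it with their published scores and
properties (`scm_reference_peptides()`), the class compositions it was
estimated from (`scm_reference_composition()`), and two physicochemical
scales used to characterize it (`scm_reference_scales()`). These fixtures
make every worked example reproducible offline and pin the implementation
to printed ground truth: all 40 rounded scores, the summary-row means, and
the card–property correlations are asserted exactly in the test suite.

```{r worked}
card <- scm_reference_card()
score_peptides(c("CFWPNRC", "QWCSRRWCT", "IKIQD"), card)
```

## Physicochemical characterization

`read_aaindex()` parses AAIndex1 flat files (records with H/D/I sections;
the I section's A/L, R/K two-row layout is remapped to residue symbols, so
downstream code never depends on that quirk). Records containing `NA` are
flagged and excluded from screening. `screen_properties()` correlates each
property with the card and flags candidates with $r > 0.5$ (strict). We
rank by signed $r$, not $|r|$: the screening question is which properties
*positively* track THP propensity, and anti-correlated properties are
deliberately de-prioritized.

Three peptide-level calculators reproduce the published property columns:

- `extinction_coefficient()`: $5500\,n_W + 1490\,n_Y + 125\lfloor n_C/2
  \rfloor$ (M$^{-1}$cm$^{-1}$ at 280 nm), i.e. cysteines assumed maximally
  paired into cystines — consistent with the disulfide-rich character of
  THPs.
- `net_charge()`: $n_R + n_K - n_D - n_E$, histidine neutral.
- `molecular_weight()`: sum of free amino-acid average masses minus
  18.00 Da per peptide bond, using the conventional two-decimal mass
  table. Published peptide MW tables differ in their mass dialect at the
  0.1 Da level, so the contract is agreement within ±0.2 Da rather than
  exactness; the bundled 40 peptides agree within 0.04 Da.

The pI and per-residue hydrophobicity columns seen in such tables are not
implemented: their pKa sets and hydrophobicity scales are not identifiable
from printed values, and guessing a scale would produce numbers that look
authoritative but verify against nothing.

## The synthetic generator

`synth_peptides()` draws peptides from per-class categorical residue
distributions: a uniform base with the enriched set (positives) or
depleted set (negatives) up-weighted by a multiplicative `bias`. Defaults
— 490 + 490 peptides of 4–10 residues, positives enriched in C/W/R and
negatives in I/K/V with bias 8 — mirror the size and the composition
contrast of the balanced THP training benchmarks, where cysteine
composition differs by roughly a factor of nine between classes. A
first-order (composition-only) model is the right fidelity here: SCM
itself sees only composition, so the generator exercises every code path
while keeping the planted signal analytically known.

What the generator does *not* emulate: motif structure (RGD/NGR),
position effects, length–class dependence, disulfide topology, and the
heterogeneous provenance of real negatives. Tests passing on synthetic
data therefore demonstrate correctness of the machinery and parameter
recovery under a known composition signal — not field performance on
curated benchmarks, which must be assessed on the real datasets.

Test and example problem sizes (490 + 490 training, 161 + 161 independent,
10-fold CV, GA defaults) were chosen to match the benchmark design the
method is used with; a full default training run takes on the order of a
second, and cross-validating the whole procedure about ten times that.

## Known limitations

- SCM is composition-blind to ordering; two permutations of one sequence
  are indistinguishable by design.
- The GA objective is evaluated on the full training set; model selection
  across repeated runs should use `cv = TRUE`, as `run_experiments()`
  does, to avoid optimistic bias.
- The cutoff search optimizes accuracy only, appropriate for balanced
  data; heavily imbalanced applications would want a cost-sensitive
  criterion.
- Dipeptide (400-entry) cards are out of scope; the implemented method is
  the amino-acid-composition variant.
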