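---
title: "Methods: wrapper gene selection with a GA-wrapped extreme learning machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrapper gene selection with a GA-wrapped extreme learning machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-class expression panels — tumour-type compendia are the canonical
case — have tens of thousands of measured genes and only a handful of
samples per class. Most genes are irrelevant to the class distinction, and
classifiers trained on the full matrix both overfit and obscure which genes
carry the signal. Wrapper feature selection attacks both problems at once:
a search procedure proposes gene subsets, and a classifier's validation
accuracy on each subset is the objective the search optimises. The
selected subset is simultaneously a classifier input and a candidate
biomarker panel.

`bcgaelm` implements one specific wrapper: a binary-coded genetic
algorithm (BCGA) whose candidate solutions are gene-inclusion bit strings,
scored by an extreme learning machine (ELM), a single-hidden-layer
feed-forward network whose hidden layer is random and whose output weights
are solved analytically. The ELM's closed-form fit is what makes the
wrapper feasible: a generational GA run evaluates thousands of subsets,
and each evaluation trains 20 classifiers.

## The classifier

For a subset of $p$ genes, training samples $x_i \in \mathbb{R}^p$ are
z-scored per feature using training-split statistics (features with zero
training variance get scale 1). A hidden layer of $H$ neurons is drawn at
random and never trained. Two parameterisations are supported:

* **sigmoid** (package default): responses
  $g_j(x) = 1/(1 + e^{-(v_j \cdot x + b_j)})$ with $v_j, b_j$ uniform on
  $[-1, 1]$;
* **rbf**: responses $g_j(x) = \exp(-\lVert x - \mu_j\rVert^2 / 2\sigma_j^2)$
  with centers $\mu_j$ sampled from the training samples and every width
  $\sigma_j$ set to the median pairwise training distance.

With $Y_h$ the $H \times n$ matrix of hidden responses and $Y$ the
one-of-$C$ target matrix ($+1$ for the true class, $-1$ otherwise), the
output weights are the minimum-norm least-squares solution

$$ W = Y\, Y_h^{\dagger}, $$

where $Y_h^{\dagger}$ is the Moore–Penrose pseudoinverse, computed by SVD
with singular values below $10^{-10}\,\sigma_{\max}$ treated as zero —
robust to the rank deficiency that is routine when $H$ exceeds the
training count. A sample is assigned the class with the maximal output
row (argmax; ties resolve to the lowest class index, a deterministic and
test-friendly rule). `tune_elm()` optionally searches a grid of hidden
counts with random restarts, minimising validation misclassifications with
squared error $\lVert Y - T\rVert^2$ as tie-break.

### Choice of activation, and a hazard of the defaults

The method's source material defines the hidden layer once as $(V, b)$
(additive nodes) and once as $(\mu, \sigma)$ (RBF nodes); which was used
is undeterminable, so both are implemented and sigmoid is the package
default. The two are **not** interchangeable at every scale. With
uniform $[-1,1]$ weights on $p$ z-scored features, the sigmoid
pre-activation has standard deviation $\approx \sqrt{p/3}$; for the
$p \approx 100$ subsets a selection run visits, the units saturate and the
classifier degrades to near-random hashing of the inputs. The RBF
parameterisation is self-scaling (its width is set from the data) and does
not suffer from this. The scaled-down experiments in the test suite
therefore run with `activation = "rbf"`; at the original study's scale the
published accuracies imply the authors' configuration did not saturate,
but the package makes no claim about which variant they ran.

Relatedly, the default hidden count `min(n_train, 100)` puts very small
training sets ($n_{\text{train}} \le 100$) exactly in the interpolation
regime $H = n_{\text{train}}$, where training accuracy is 100% by
construction and generalisation is erratic. This default mirrors the
regime of the original 144-sample training splits (where $100 <
n_{\text{train}}$); for small data, set `n_hidden` explicitly or use
`tune_elm()`.

## The objective

A chromosome $F \in \{0,1\}^L$ selects the genes at its set bits. Its
evaluation (`evaluate_subset()`) repeats, for each of `n_splits = 20`
seeded splits: stratified 75/25 partition, ELM training on the training
part (a fresh random hidden layer per split, so the score averages over
initialisation noise), overall accuracy — correct/total — on the test
part. With $\bar\eta_a$ the mean of the 20 test accuracies, the fitness is

$$
f \;=\;
\begin{cases}
\bar\eta_a + \dfrac{\omega_f}{\sum_i F_i}, & \bar\eta_a > d \\[4pt]
\bar\eta_a, & \text{otherwise,}
\end{cases}
$$

with defaults $\omega_f = 1$ and $d = 0.98$. Below the accuracy threshold
$d$ the search is driven purely by accuracy; above it, smaller subsets
strictly dominate larger ones at equal accuracy. The branch condition is
strict (`>`), with the lower branch taken at equality.

Two protocol details are deliberate strengthenings of a looser original
description, documented here as such:

* **Stratified splits.** With as few as 8 samples in a class, an
  unstratified 25% draw can leave a class entirely out of training, making
  prediction for it undefined. Splits are stratified per class
  ($\lceil 0.75\, n_c \rceil$ to training, at least 1).
* **Shared splits within a generation.** Whether the 20 splits are
  redrawn per chromosome was unspecified. By default all chromosomes of a
  generation are scored on identical splits (seeds derived from
  `(master_seed, generation)`), so fitness comparisons within a generation
  are not confounded by split luck; `split_mode = "independent"` restores
  fully independent draws.

## The search

Generational loop with population 200 (default), crossover probability
0.80, mutation probability 0.20, normalized geometric ranking selection
with $q = 0.01$, 50 generations, initial chromosomes carrying 20–200
genes:

1. **Ranking/selection.** Rank $r$ (1 = best; ties broken by fewer
   selected genes, then insertion order) receives parent-selection
   probability $q'(1-q)^{r-1}$, $q' = q / (1 - (1-q)^N)$.
2. **Hybrid crossover.** Each parent pair, with probability 0.80,
   produces four offspring — two by uniform crossover, two by two-point
   crossover (half-open segment $[i, j)$, cuts drawn without replacement
   from $\{0..L\}$) — all four are scored with the full repeated-split
   objective (no cheap proxy), and the best two replace the parents.
3. **Mutation.** With probability 0.20 an offspring is mutated; mutation
   flips each bit independently at rate $1/L$ (one expected flip). The
   published "mutation probability 20%" carries no granularity; a per-bit
   rate of 0.20 on a 16,063-bit string would randomise ~3,200 genes per
   event and destroy convergence, so the per-offspring reading is used.
4. **Repair.** Any all-zero chromosome (possible after crossover or
   mutation) gets one uniformly chosen bit set — the objective divides by
   the set-bit count.
5. **Elitism.** The best individual ever seen re-enters the next
   generation unchanged, making best-so-far fitness non-decreasing.

Termination: a fixed generation budget, or early stop once the best mean
validation accuracy reaches `target_accuracy`. Every stochastic choice
derives from a single master seed through a splittable mixing function, so
an entire run — including file outputs — is byte-reproducible.

## The synthetic world

`generate_dataset()` plants `n_informative` discriminative genes among
`n_noise` null genes over `n_classes` classes with configurable per-class
sample counts. Each informative gene receives a random non-constant
binary class pattern: classes at the "high" level sit `effect_size`
noise-SD units above the "low" level, so different informative genes
separate different class subsets (block-differential structure). Noise
genes are i.i.d. Gaussian across all classes; an optional log-normal flag
exponentiates the matrix for intensity-like marginals. Gene order is
shuffled, and the planted truth (ids and class-mean matrix) is returned
for scoring recovery.

Defaults (4 classes × 15 samples, 10 informative among 490 noise genes,
effect size 5) are the scaled-down regime the acceptance experiments
state: large effects and modest dimensionality, so that a
population-30/15-generation run can demonstrably recover the planted
genes in minutes. The generator emulates the *shape* of the original
regime (few samples per class, mostly irrelevant features, imbalance if
requested) but none of its microarray artifacts — no probe-level noise,
batch effects, or realistic intensity distributions. A green recovery
test establishes that the search mechanism works on a well-posed planted
problem; it says nothing about accuracy on real tumour data.

## What the scaled-down experiments assert, and how

* **Recovery** (acceptance 6): with the world above, population 30 and 15
  generations, the best chromosome averaged over 3 master seeds reaches
  recall ≥ 0.7 of the planted genes and mean validation accuracy ≥ 0.9.
  The run uses the RBF hidden layer for the reason given above.
* **Chance-level control** (acceptance 7): the same pipeline on
  label-permuted data must sit at chance (1/4). Two biases have to be
  excluded from the measurement. The GA's best-ever score is a maximum
  over ~10³ noisy evaluations (winner's curse); and, more fundamentally, a
  wrapper that screens 500 genes on 60 fixed samples finds genes whose
  chance correlations with the permuted labels hold across the *whole*
  dataset, so even re-evaluation on fresh internal splits stays well above
  chance (measured: ≈ 0.40 on this world) — the classic selection-bias
  result for feature selection performed outside the evaluation loop.
  The assertion therefore scores the selected subset against an
  independent re-permutation of the labels — a null the search never saw
  — and compares it to 0.25 within 3 binomial standard errors of the
  total test-sample count. The same phenomenon is why internal
  cross-validation accuracies of any wrapper method (this package
  included) must be read as optimistic unless validated on external data.
* **Determinism** (acceptance 8): two `cmd_select()` runs from one master
  seed produce byte-identical gene lists and JSON reports; a third run
  with a different seed differs (control). Asserted on a smaller config
  (200 genes, population 10, 4 generations) to fit its time budget.
* The effect-size property of the generator runs the full pipeline on a
  reduced world (150 genes, population 16, 8 generations, 10 splits,
  5 seeds per effect size) purely for runtime; assertions are on means
  across seeds. Selection *precision* is monotone in effect size, and
  recall at effect sizes 3 and 5 exceeds recall at 1 — but full recall
  monotonicity is **not** asserted, because it is not a property a
  minimal-subset selector has: once the effect is strong enough that
  accuracy saturates, the parsimony branch of the objective deliberately
  discards planted genes that are redundant given the ones already
  selected, and measured recall can dip (at this scale: mean recall
  0.20 / 0.50 / 0.35 over effect sizes 1 / 3 / 5, while precision rises
  0.06 / 0.17 / 0.20). Recovering *every* planted gene is the goal of a
  screening method, not of a minimal discriminative panel.

## Numerical choices and degenerate inputs

* Pseudoinverse cutoff $10^{-10}\sigma_{\max}$; z-scoring guard (zero
  variance → scale 1); argmax ties → lowest class index.
* Single-class training sets are an error (the decision rule is
  undefined), as are all-zero chromosomes, empty validation sets, and
  expression files with missing, non-numeric or duplicated-id rows (no
  imputation, no deduplication — positional bit↔gene mapping must stay
  exact).
* Two-point crossover draws cuts from $\{0..L\}$ without replacement so
  the swapped segment is never empty; `cuts = c(0, L)` is the full swap.

## Known limitations

* The fitness of near-threshold chromosomes is noisy at 20 splits; the
  shared-splits default reduces ranking noise but does not remove it.
* The sigmoid variant degrades for wide feature subsets (saturation,
  above); prefer rbf or tune the weight scale via `n_hidden`/restarts.
* Selection with $q = 0.01$ exerts little pressure in small populations
  (at $N = 30$, rank-1 and rank-30 probabilities differ by only ~25%);
  the published value targets $N = 200$.
* Runtime scales linearly in population × generations × splits; the
  full published configuration (200 × 50 × 20 on 16,063 genes) is a
  multi-day run and is intentionally out of the test envelope.
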