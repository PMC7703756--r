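---
title: "Learning sample weights for term-aware co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning sample weights for term-aware co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Guilt-by-association function prediction ranks candidate genes for a GO term
by their similarity to genes already annotated with it. With expression
data, the similarity is co-expression, classically the Pearson correlation
(PCC) over *all* samples of a compendium. In a heterogeneous compendium most
samples say nothing about any particular biological process, and their noise
dilutes the correlations that matter. `mlcoex` learns a per-term,
per-sample, non-negative weight vector so that the weighted co-expression of
co-annotated gene pairs separates as far as possible from that of mixed
pairs, and so that uninformative samples receive weight exactly zero.

All similarities operate on the centred, unit-norm expression rows
$\tilde{x}_i = (x_i - \bar{x}_i)/\lVert x_i - \bar{x}_i \rVert$ produced by
`center_scale()`; on this substrate the unweighted inner product equals the
PCC of the original vectors, which is both a convenient baseline identity
(tested to $10^{-9}$) and the reason the weighted *inner product*
$S_w(i,j) = \sum_m w_m \tilde{x}_{im} \tilde{x}_{jm}$
is preferred over a weighted correlation: it is linear in $w$, which keeps
the objective and its gradient cheap and exact.

For a term with positive gene set $P$ (the annotated training genes) and
negative set $Q$, gene pairs fall into positive–positive, positive–negative
and negative–negative classes. Only the first two enter the objective: a
pair of genes *not* annotated with the term may well be co-expressed because
of some *other* shared process, so its similarity is uninformative here.
Separability is quantified by the Welch two-sample t-statistic between the
p–p and p–n similarity distributions,
$$t(w) = \frac{\mu_{pp}(w) - \mu_{pn}(w)}
             {\sqrt{\sigma^2_{pp}(w)/N_{pp} + \sigma^2_{pn}(w)/N_{pn}}},$$
and the weights minimise
$-\alpha\, t(w) + (1-\alpha) \sum_m w_m$ subject to $w_m \ge 0$.
The statistic is used purely as a separability score — the similarity values
are neither independent nor Gaussian, but no p-value is ever taken from
$t$, so those assumptions are not needed.

Two structural facts shape everything downstream:

* **Scale invariance.** $\mu$ is linear and $\sigma$ homogeneous of degree
  one in $w$, so $t(cw) = t(w)$ for all $c > 0$ (a tested invariant). The
  separability term therefore only determines the *direction* of $w$; the L1
  term alone fixes the scale, shrinking it steadily while zeroing
  coordinates whose contribution to $t$ does not justify their L1 cost.
* **Moment reduction.** With $p = \sum_{i \in P}\tilde{x}_i$ (per sample),
  $G^P = X_P^\top X_P$, $G^Q = X_Q^\top X_Q$ and $H = (X_P^2)^\top X_P^2$,
  the pair sums collapse to
  $U = (p^2 - \mathrm{diag}\,G^P)/2$, $V = p \circ q$,
  $M_{pp} = ((G^P)^2 - H)/2$, $M_{pn} = G^P \circ G^Q$ (elementwise), so
  that $\mu = w^\top U / N$ and the unbiased variance is
  $(w^\top M w - N\mu^2)/(N-1)$. Evaluating $t$ and its analytic gradient
  costs two matrix–vector products per iteration regardless of the number
  of gene pairs. The reduction is verified against brute-force pair
  enumeration to $10^{-9}$ on over a hundred random instances.

## Optimisation choices

Non-negativity is enforced by the box constraint of `optim`'s L-BFGS-B
(lower bound 0 per coordinate); how the original BFGS formulation enforced
the constraint is not something the formulation itself pins down, and a
projection-free reparameterisation (softplus or squaring) would change the
geometry of the L1 term, so the bound-constrained quasi-Newton is the
cleanest realisation. Initialisation is all-ones — by the inner-product/PCC
identity this starts the search exactly at unweighted-correlation behaviour
— and fitting involves no randomness at all.

Because of scale invariance the optimizer never "converges" in the
textbook sense: once the direction has settled, the L1 term keeps shrinking
the overall scale at an ever-slower rate until the iteration cap
(`maxit`, default 200) or the relative-improvement threshold (`factr`)
stops it. Such fits are returned with `converged = FALSE` and are entirely
usable: k-NN classification depends only on similarity *rankings*, which
depend only on the weight direction, and the "selected sample" count uses a
threshold relative to the largest weight
($\varepsilon = 10^{-8} \max_m w_m$) precisely so that global shrinkage
does not masquerade as sparsity. Degenerate evaluations (both class
variances below $10^{-12}$) define $t = 0$ when the means also coincide,
which keeps the all-zero weight vector well-defined instead of producing
0/0.

Unbiased ($N-1$) variances are used in both the implementation and the
independent test oracle; at realistic pair counts the difference from the
population convention is far below every tolerance used here.

## Global variant and pair subsampling

The non-term-specific variant shares one weight vector across terms by
redefining p–p as "the two genes share at least one informative GO term"
and p–n as "they share none". Terms with zero information content (the
root, or anything annotated to every gene) are excluded from "sharing",
otherwise all annotated pairs would be p–p; pairs in which *neither* gene
carries an informative annotation are the n–n analogue and are excluded.
This pair relation has no low-rank structure, so its moments come from a
seeded uniform subsample of pairs per class (default 20 000), rescaled to
the population pair counts — the same estimator that serves as the memory
fallback when the sample dimension makes the dense $f \times f$ moment
matrices unreasonable (guard at $f > 5000$ by default). The exact moments
are the default and the primary tested path.

## Prediction and evaluation

`knn_scores()` scores a test gene by the fraction of its $k$ nearest
training genes annotated with the term, with ties broken by ascending
training index (deterministic). Mutual Rank converts any symmetric
similarity into the geometric mean of reciprocal neighbour ranks (average
ranks under ties), and may also be applied on top of the learned similarity
(`mr_on_mlc()`). ROC AUC uses the rank-based Mann–Whitney form with average
ranks, matching an exhaustive pair-counting oracle, and term averages may be
weighted by Resnik information content, $-\ln$ of a term's relative
annotation frequency after true-path propagation, to emphasise specific
terms.

`nested_cv()` splits genes (never samples) into 3 outer folds and, within
each training set, 3 inner folds that select $k$ — and $\alpha$ for the
learned metric — by mean term-centric AUC; the outer test genes touch
nothing during fitting or tuning. The $k$ grid is
$\{1, 3, 5, 11, 21, 51\}$ capped at the training size, and the $\alpha$
grid defaults to $\{0.5, 0.9, 0.99, 0.999\}$; neither grid is prescribed by
the formulation, so both are configurable. A term enters a fold only with
at least `min_pos` (default 5) positive training genes — the objective
itself needs two positives for a p–p variance, and five keeps the variance
estimates from being vacuous — and terms single-classed among the test
genes are skipped and recorded so that fold averages compare like with
like across methods. The hybrid classifier uses, per term, the Mutual Rank
predictions when MR's training AUC strictly exceeds 0.8 and the learned
metric's otherwise. All randomness (fold splits, pair subsampling,
simulation, permutations) flows from one root seed through named
substreams (`substream_seed()`), making every stage independently
reproducible and full runs bit-identical.

## What the simulator emulates — and what it does not

`simulate_dataset()` realises the validation design in which each of
`n_terms` terms has a disjoint block of informative samples: within term
$\ell$'s block, its positive genes follow the one-factor model
$x_{im} = \sqrt{\rho}\, s_m + \sqrt{1-\rho}\,\varepsilon_{im}$ with a
shared per-sample factor $s$, giving every positive pair correlation
$\rho$ over the block (default 0.7) and zero elsewhere; everything else is
independent standard noise. The one-factor Gaussian form is the minimal
generative law achieving a target within-block correlation; the original
design is stated only qualitatively, so noise level (unit), positives per
term (50) and contiguous blocks are this package's explicit stand-ins.
Library defaults are desk-scale — 1000 genes, 600 samples, 3 terms, blocks
of 100 — and `paper_scale_spec()` provides the 7000 × 3000 preset for full
replication. Data are emitted directly in log-space; count-level realism
(negative binomial sampling, zero inflation, batch structure) is
deliberately out of scope, so passing tests demonstrate the estimator's
behaviour under its own assumptions, not robustness to technical artefacts
of real RNA-seq.

One consequence of the desk scale deserves honesty: with 100 informative
samples out of 600 and $\rho = 0.7$, a positive pair's expected inner
product ($100 \times 0.7 / 600 \approx 0.117$) stands almost three standard
errors ($\approx 1/\sqrt{600}$) above the mixed-pair distribution, so the
*unweighted* PCC classifier already saturates the term-centric AUC and the
learned metric can only match it, not beat it — the AUC advantage of sample
selection emerges at compendium scale (informative fractions of a few
percent), not here. What the desk-scale run does demonstrate, and what the
acceptance suite asserts, is sample recovery (in-block weights an order of
magnitude above out-of-block, significant rank-sum and Fisher enrichment in
every seed), the convergence of the learned metric to PCC when the
informative block spans all samples, and the permutation null.

## Numerical and protocol choices, in brief

* Preprocessing follows the depth filter (≥ $10^7$ mapped reads; column
  sums proxy when no metadata is given), the max-expression (≥ 100) and
  median-expression (≥ 1) gene filters on raw counts, then
  $\log_2(\cdot + 0.125)$ — strict-less-than removals, in that order
  (the gene filters depend on the retained samples; a property test shows
  order matters). The log base only rescales and is configurable. Whether
  counts should be depth-normalised before the gene filters is not
  specified by the source pipeline; filters apply to raw counts here.
* Batch handling: studies with a single sample are dropped;
  `batch_correct()` offers per-batch location/scale standardisation, a
  pass-through for pre-corrected matrices, and an `sva::ComBat` hook.
* Annotation propagation closes gene–term sets over `is_a` and `part_of`
  within the biological-process namespace; IEA-evidence and NOT-qualified
  rows are dropped at parsing.
* Permutation-null and acceptance runs use $\alpha \in \{0.9, 0.99\}$ and
  `maxit = 100` inside the nested CV: the null is insensitive to tuning
  breadth, and the weight direction settles long before the L1 scale
  shrink would terminate. These are the package's run-scale choices and
  are stated wherever results are produced.

## Known limitations

Negative co-expression is penalised, not exploited: a gene anti-correlated
with the positives is pushed away even though sign-flipped co-regulation
can be biologically real. Very frequent terms inherit the method's known
weakness — n–n pairs are never tuned, so abundant positives generate false
positives. Term-specific fitting treats terms independently and cannot
exploit the ontology's label correlations beyond what propagation injects.
And the simulator's Gaussian, batch-free world says nothing about
robustness to count noise or study effects; conclusions about real
compendia require the full-scale, real-data pipeline.
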