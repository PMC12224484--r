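---
title: "Classifying depression phenotypes from connectome edges: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying depression phenotypes from connectome edges: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Depression is phenotyped many different ways in large community cohorts —
by medication history, by lifetime diagnostic interviews, by current
symptoms, by recurrence — and the case sets these definitions produce
overlap heavily without coinciding. `connridge` implements a complete,
reproducible pipeline for asking how well brain connectomes separate cases
from matched controls under each definition, whether restricting cases by
self-reported childhood trauma changes the answer, and which subnetwork
connections the classifiers rely on. Because the population imaging data
this kind of study draws on are access-restricted, the package ships a
synthetic cohort generator that reproduces the *statistical shape* of such
data — overlapping phenotypes, a trauma score with meaningful thresholds,
and connectomes with block-structured covariance — so every stage of the
pipeline can be exercised and tested end to end.

## The classifier

The unit of analysis is an edge vector: a subject's symmetric $N \times N$
connectivity matrix reduced to its $N_e = N(N-1)/2$ upper-triangle entries
(1,485 features for the 55-node functional connectomes, in row-major pair
order). For labels $y_i = \pm 1$ the model is logistic ridge regression,

$$\min_{b,\,\beta}\; \frac{1}{n}\sum_{i=1}^n
\log\!\left(1 + e^{-y_i(\beta^\top x_i + b)}\right)
+ \lambda \lVert \beta \rVert_2^2 ,$$

with the intercept $b$ unpenalized. The mean-scaled loss is a deliberate
choice: it makes one $\lambda$ grid comparable across the very different
sample sizes the phenotypes produce. The default grid is 13 half-decade
log-spaced points from $10^{-3}$ to $10^3$: wide enough to span
near-unpenalized fits and near-total shrinkage, with half-decade spacing
as a reasonable resolution for accuracy-based selection.

Numerically, the optimum of this penalized objective lies in the row space
of the design, so the solver reduces the problem through a thin SVD
($X = UDV^\top$, $\beta = Vw$, $\lVert\beta\rVert = \lVert w\rVert$) and
runs damped Newton iterations in $\min(n, p) + 1$ dimensions — exact, and
fast when $p \gg n$ as here. Convergence is declared at gradient norm
below $10^{-8}$; the line search accepts steps that do not increase the
objective beyond float resolution, because near the optimum the quadratic
improvement of a full Newton step is smaller than the representable
difference in the loss. Along the $\lambda$ path, fits warm-start from the
previous penalty (descending). All-zero feature columns (which
z-normalization produces for zero-variance features) receive exactly zero
coefficients, since they lie outside the row space.

## Matched samples and nested cross-validation

Cases are subjects carrying the phenotype flag; controls are subjects
carrying *no* flag at all. Subjects with comorbid-disorder exclusions are
removed from both pools first, and an optional childhood-trauma threshold
(`ctq >= tau`, inclusive) filters the cases *before* matching, so the
sample is always 1:1. Matching is greedy nearest-neighbour without
replacement: cases in ascending id order, sex as a hard constraint, and
the control minimizing
$|\Delta\text{age}|/\sigma_{\text{age}} + |\Delta\text{ICV}|/\sigma_{\text{ICV}}$
(standard deviations over the control pool). The combination rule is a
design decision: nearest-neighbour matching needs the two covariates on
one scale, and pool-standardized absolute differences treat age and ICV
symmetrically. Ties break by ascending control id, which makes
the whole construction deterministic and order-invariant.

Evaluation is a pair-level nested 6×5 cross-validation. Pairs (never
individuals) are dealt into six outer folds; within each outer-training
set, into five inner folds — so train, validation, and test sets all stay
1:1 and matched. Each inner fold selects the $\lambda$ maximizing
validation accuracy (ties resolve to the largest penalty, i.e. toward
parsimony), with feature z-normalization refit on each inner-training set
(denominator $n-1$); the 30 inner-optimal models are each evaluated on
their untouched outer test fold. The 30 models are kept as 30 — they are
not refit on the full outer-training set — so performance is estimated
from 30 evaluations rather than 6, and the downstream stability filter
gets exactly this ensemble to vote over. Outer-test subjects never enter normalization statistics or
penalty selection; the test suite asserts this structurally. Normalization
could defensibly be refit per inner fold or once per outer-training set;
per-inner-fold is used as the stricter (strictly leak-free for the
validation folds) choice. Sex-stratified analyses re-run the whole
construction (including
matching) inside one stratum rather than subsetting an all-sex sample.

## Stable features, Jaccard overlap, and block enrichment

A feature is *important* if, in every one of the 30 models, its
coefficient (a) ranks in the top half by magnitude — rank at most
$\lfloor p/2 \rfloor$, with ties broken by ascending feature index, a
convention this package fixes since the criterion does not address ties —
and (b) carries the same nonzero sign. Feature sets from different runs
are compared with the Jaccard index $|A \cap B| / |A \cup B|$ (two empty
sets count as identical); printed tables use half-up rounding to four
decimals.

Block-level inference asks whether a subnetwork pair holds more or fewer
important edges than chance. With $K$ important edges among $N_e$, block
capacities $S_{ij} = n_i n_j$ (off-diagonal) or $n_i(n_i-1)/2$ (diagonal),
and observed counts $O_{ij}$, the test is the hypergeometric tail:
lower ($P[X \le O_{ij}]$, "fewer") when $O_{ij} \le K S_{ij}/N_e$ —
including exactly at the expectation — and upper ($P[X \ge O_{ij}]$,
"more") otherwise. Benjamini–Hochberg correction is applied across the 21
testable blocks of *one* model (zero-capacity blocks, e.g. the diagonal of
a singleton subnetwork, are excluded from the family); correcting within
one model matches how such block matrices are usually annotated, and the
correction family is otherwise unspecified. The signed block summary

$$\beta^{\text{norm}}_{ij} = \frac{\sum_{e \in \text{block}(i,j) \cap
\text{important}} \bar\beta_e}{\sum_{e} |\bar\beta_e|}$$

(mean coefficients $\bar\beta$ over the 30 models) is this package's own
formulation of a block-level predictive-direction summary: its sign says
whether the block pushes predictions toward case or control, and its
magnitude is a small fraction of the model's total coefficient mass. Users
comparing against other implementations should treat $\beta^{\text{norm}}$
as package-defined.

## What the synthetic generator emulates

Each subject gets covariates (age uniform on 45–80 years; sex; ICV from
sex-specific normals around 1.40/1.55 litres), a latent standard-normal
liability, six phenotype flags, a childhood-trauma score, an exclusion
flag (2% by default), and on demand functional and structural connectomes.

**Phenotypes.** `ever` is liability above a sex-specific threshold;
`current` and `ever_severe` split a higher-liability tier by presence of
current symptoms — which makes them disjoint, following the textual
definition ("current symptoms absent") even though published overlap
tables suggest the operational definitions overlapped; a
`severe_current_overlap` switch restores overlap for users who prefer the
tables' behaviour. `recurrent` requires `ever` plus at least two episodes;
`drug` and `mdd_narrow` are liability-dependent Bernoulli draws whose
intercepts are solved at configuration time to hit their target
prevalences. Sex-specific thresholds are solved in closed form so the
female share among cases is 2/3 while liability stays standard normal.
Default prevalences (ever 0.25, severe tier 0.10, drug 0.05, narrow
0.065) are deliberately *larger* than the real questionnaire phenotypes
(where the currently-depressed group is ~1.4%): they preserve the severity
ordering while letting desk-scale cohorts of a few thousand subjects
yield hundreds of matched pairs. The
generator refuses to produce a cohort of 1,000+ subjects in which any
phenotype has zero cases.

**Trauma score.** The CTQ score is the exact mean of five item scores in
$[0,1]$, marginally a zero-inflated Beta coupled to liability through a
Gaussian copula (correlation 0.35). The marginal's three parameters are
solved at configuration time (1-D integration + root finding) so that
among cases the thresholds 0.2/0.4/0.6 fall at approximately the
50th/70th/80th case percentiles; a Monte-Carlo test checks the
calibration to within ±5 percentile points at $n = 10^4$.

**Functional connectomes.** Controls' time series (200 points by default)
are multivariate normal with an exchangeable-block correlation: 0.3
within subnetworks, 0.05 between, over a 10/9/12/8/8/8 split of 55 nodes
labelled SMN, VN, EC_AN, CON, DMN, eDMN. The true per-subnetwork node
counts of the real 55-node partition are only published graphically, so
only the partition *structure* is reproduced; sizes are configurable. For
cases, target-block correlations shift by `delta` *on the Fisher-z
scale* (mapped back through tanh, keeping correlations valid), optionally
amplified by `1 + ctq_slope * ctq`. The default planted block is within
VN. Full connectivity is the Fisher-z sample correlation; partial
connectivity is derived from the Tikhonov-regularized inverse sample
correlation (ridge strength 0.5 by default, a common choice for heavily
regularized network matrices), both exactly symmetrized with zero
diagonal. Covariances are validated by
Cholesky; an infeasible configuration (e.g. between-block correlation
exceeding within) raises a generation error.

**Structural connectomes.** A shared 85-node base topology (edge presence
0.6) with per-subject edge reliability 0.9 (absent edges are exact
zeros), log-normal weights per channel with an edge-level noise component
shared across the six channels, and an optional case effect `delta_s` on
the log-weights of a designated node set. The six channels are abstract
correlated weightings named after the usual diffusion metrics (SC, FA,
MD, ICVF, ISOVF, OD); no biophysical model is attempted — the classifier
only ever sees edge weights. Structural channels pass through group
proportional thresholding (edge kept iff nonzero in at least
$\lceil 2/3 \cdot n \rceil$ subjects, an inclusive reading of "at least
2/3"); dense functional matrices are never thresholded.

**What it does not emulate.** No raw image simulation, no ICA, no
tractography, no attempt to match real effect sizes, no subject-level
covariance heterogeneity beyond sampling noise, and no spatial structure
within subnetworks. Consequently, passing tests demonstrate that the
pipeline's statistics behave as designed under a known ground truth — not
that real connectomes carry comparable signal. In particular the planted
effects used in the tests are strong: a within-block Fisher-z shift of
0.5 at 200 time points is ~7 per-edge standard errors, so classifier
accuracies saturate quickly, which real studies of psychiatric phenotypes
never do.

## Determinism and problem sizes

Every stochastic step runs under explicit seeds: the cohort seed fixes
covariates and phenotypes; each subject's connectome is drawn under a
sub-seed derived from the cohort seed and the subject's position, so
matrices are bit-identical whether one subject or the whole cohort is
materialized; fold plans take their own seed. Two runs with identical
configuration are byte-identical.

The test suite and the acceptance script choose deliberately modest
problem sizes — cohorts of 450–2,600 subjects, 30–300 matched pairs, five
recovery replicates, five seeds per effect size on a 60-pair grid — sized
so the full pipeline (generation, matching, 390 model fits per nested CV,
selection, enrichment) is exercised many times over in minutes. The
chance-level contract uses the full configuration of interest: 200
matched pairs, 1,485 features, the complete 13-point grid.

## Known limitations

* The stability filter ("top half, same sign, in all 30 models") admits
  noise features whose sample correlation with the labels is strong in a
  given cohort, because the 30 models share most of their training data.
  Such features are spatially *clustered* (edges within a subnetwork are
  correlated), so the hypergeometric block test — which assumes important
  edges are drawn independently — can occasionally flag a non-planted
  block. This is a property of the statistic itself, not a defect of the
  implementation; the recovery tests quantify it.
* Greedy nearest-neighbour matching is order-dependent by construction;
  determinism is guaranteed, global (e.g. Hungarian-algorithm) optimality
  is deliberately out of scope.
* The partial-correlation construction (regularized precision of the
  sample correlation) is one of several possible readings of the
  upstream tooling; its ridge strength is configurable.
* `beta_norm` is package-defined (see above) and not comparable across
  implementations that aggregate differently.
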