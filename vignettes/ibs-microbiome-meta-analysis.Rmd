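---
title: "Cross-cohort meta-analysis of the IBS gut microbiome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort meta-analysis of the IBS gut microbiome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Irritable bowel syndrome (IBS) case-control microbiome studies disagree with
each other far more than any of them disagrees internally: cohort explains an
order of magnitude more community variance than health status. `ibsmeta`
implements the analysis strategy built for exactly this situation — estimate
disease effects *within* each cohort, demand cross-cohort consistency, and
only then pool — together with the downstream analyses that interpret the
resulting signature species: a compositional co-occurrence network, classifier
transfer across cohorts, an antibiotic-response probability shift, diet
association screening, and a functional-profile consistency rule. A seeded
synthetic-data generator with planted ground truth makes every stage testable
without access to raw sequence data.

## The discovery model

For each species in each cohort, the case-control difference is summarised by
Hedges' G, the bias-corrected standardised mean difference on relative
abundance. With group sizes $n_1$ (controls) and $n_2$ (cases),

$$ s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}, \qquad
   d = \frac{\bar x_{HC} - \bar x_{IBS}}{s_p}, \qquad
   g = \left(1 - \frac{3}{4(n_1+n_2-2)-1}\right) d, $$

with sampling variance $\widehat{var}(g) = \frac{n_1+n_2}{n_1 n_2} +
\frac{g^2}{2(n_1+n_2)}$. The sign convention is fixed throughout the package:
positive $g$ means higher in healthy controls, i.e. depleted in IBS.

Candidate species must behave consistently across the 14 discovery cohorts
before any pooling happens: a depleted candidate needs $g > 0.1$ (the
conventional small-effect floor) in at least 7 cohorts and $g < -0.1$ in at
most 3; enriched candidates mirror this. Cohorts where a species is
undetected, or where its pooled standard deviation is zero, count toward
neither tally. The thresholds are absolute counts by default; a
`proportional_support` switch rescales them by the number of cohorts in which
the species was actually observed, for designs with very uneven detection.

Candidates are then pooled under the random-effects model
$g_i \sim N(\mu, v_i + \tau^2)$. The restricted-maximum-likelihood estimate of
$\tau^2$ is the default (iterated fixed point from the DerSimonian-Laird
start, convergence $|\Delta\tau^2| < 10^{-10}$, at most 100 iterations, DL
fallback with a warning); the closed-form DL estimator is selectable and is
also what the heterogeneity statistics $Q$ and
$I^2 = \max(0, (Q-(k-1))/Q)\cdot 100$ are based on. One Benjamini-Hochberg
correction is applied jointly over depleted and enriched candidates — a
single testing family, since the final species count is reported over the
union — and a species is retained as a signature when $q < 0.1$ **and**
$p < 0.05$. $I^2$ below 25 is classed as low heterogeneity, below 50 moderate,
otherwise high, with boundaries assigned upward.

Two validation views accompany discovery: Spearman correlation of the pooled
estimates against per-species effects in an external cohort, and concordance
between effects computed on relative abundance versus on centred log-ratio
(CLR) transformed counts. The CLR uses a pseudocount of 1 count by default —
the most common convention; the original analysis does not state one — and is
always computed per cohort, never on concatenated cohorts.

## Compositional network

Correlations among signature species are estimated with SparCC, which infers
basis (absolute) abundance correlations from compositional counts via
log-ratio variances: per resampling round, fractions are drawn from
Dirichlet(counts + 1), the variation matrix
$t_{ij} = \mathrm{var}\log(f_i/f_j)$ is formed, basis variances solve
$\sum_j t_{ij} = (D-2)\omega_i + \sum_j \omega_j$, and pairs whose estimated
$|\rho|$ exceeds 0.1 are iteratively excluded from the system (at most 10
times) to repair the sparsity assumption. The reported matrix is the
element-wise median over 20 rounds, clipped to $[-1, 1]$. We chose the
original count-resampling algorithm rather than Pearson on CLR values because
SparCC defines its own compositional correction; a `clr_pearson` method
switch provides the direct alternative for comparison.

Edge significance comes from an explicit permutation null — every species'
counts permuted independently across samples, the full estimator recomputed —
with two-sided pseudo p-values $p = (1 + \#\{|\rho^\ast| \ge |\rho|\})/(1+B)$,
so $1/(B+1)$ is the smallest attainable value; the upstream tooling describes
its null loosely as bootstrapped, and we label ours explicitly as permutation
p-values. Edges are kept at BH FDR < 0.01 over all unordered pairs. Modules
are Louvain communities (resolution 1.0, seeded) on the positive-edge
subgraph, with edge weight $\rho$; negative edges stay in the network and its
exports but are excluded from the modularity objective, which is defined for
non-negative weights. Isolated nodes become singleton modules. Note the
granularity interaction: with $B$ permutation rounds and $m$ pairs, the
smallest reachable q-value is $\frac{m}{(B+1)k}$ for $k$ floor-level pairs, so
an edge FDR of 0.01 needs several hundred rounds unless many pairs share the
floor.

## Community-level tests

Bray-Curtis (abundance-weighted) and binary Jaccard (presence/absence)
dissimilarities feed a PERMANOVA with *marginal* sums of squares — each term
assessed given all others via the full-versus-reduced trace formulation —
with free permutation of observations and p-values bounded below by
$1/(B+1)$. Samples missing any model term are dropped listwise per model with
a logged count, since real cohort metadata is incomplete. Marginal sums of
squares are not exactly additive across correlated terms; single-term models
reduce exactly to classic one-way PERMANOVA and are verified against a
brute-force Gower-centring oracle in the test suite.

## Classifier validation and the treatment shift

Random-forest classifiers are tuned by out-of-bag error over a grid
(`mtry` 6-60 by 2; `ntree` 100-2000 by default; both arguments), ties broken
toward smaller `ntree` then smaller `mtry`, everything seeded. Three schemes
quantify transfer: cross-cohort (train on each cohort, test on every other —
one fold per ordered pair), leave-one-cohort-out (train on the concatenated
rest), and a stratified 60/40 within-cohort split. The feature space is the
union of signature species with absent species filled as zero relative
abundance. AUC is the Mann-Whitney probability that a random case outscores a
random control, ties counted one half.

The treatment analysis asks how far therapy moved patients toward the healthy
profile: a forest is tuned on healthy controls versus pre-treatment patients;
pre-treatment samples are scored *out-of-bag* (avoiding resubstitution
optimism — the conservative choice, flagged in the report and switchable),
post-treatment samples by the fitted model; the probability distributions are
compared with a two-sided Wilcoxon rank-sum test. A per-signature table of
after-versus-before Hedges' G summarises which species moved toward the
healthy direction.

## Diet and function

Food-frequency categories are mapped through a ten-level monotone weight
vector (default 0, 0.1, 0.5, 1, 2, 3.5, 5.5, 7, 10, 14 — a servings-per-week
style stand-in; the original weighting is cited but not reproduced in our
source, and because the downstream screen is Spearman, only monotonicity
matters). Weighted intakes are correlated with signature-species abundances
using Spearman's rho with average ranks and a t-approximation p-value; one BH
family covers the entire item-by-species grid. Food items are clustered on
their rho profiles (Euclidean distance, complete linkage), and alcohol-style
contrasts use Wilcoxon for continuous intake or Fisher's exact test for
binary drinking flags.

Functional tables (pathways, CAZymes, EC numbers) are analysed per cohort by
ordinary least squares of untransformed relative abundance on status plus
cohort-specific covariates (an arcsin-square-root switch exists but is off by
default, since the source analysis states no transform), BH-corrected within
each cohort-by-category family. Across cohorts, a function is `overlapping`
when its status coefficient keeps one sign everywhere it was evaluated
(all-zero functions are unevaluated, not zero-effect), and `significant` when
it additionally reaches $q < 0.1$ or $p < 0.05$ somewhere.

## What the generator emulates — and what it does not

`sim_config()` defines the study conditions: 14 cohorts of 50 controls and 50
cases; 300 species with log-baselines $N(0, 2)$; per-cohort composition
offsets ($sd = 0.5$); 30 signature species, split evenly depleted/enriched,
with true log-scale effect 0.8 and between-cohort heterogeneity
$\tau = 0.2$ (so $\tau^2 = 0.04$); three 8-species blocks at within-block
latent correlation 0.7 for network tests; within-sample latent noise
$sd = 1.4$; multinomial counts at depths drawn uniformly from 5,000-50,000.
The noise scale was set so that per-cohort planted $|G|$ lies mostly in the
0.2-0.6 small-effect regime the consistency filter targets (median 0.40, 75%
inside the band). Latent log-normal abundances pass through a softmax and a
multinomial, so counts are genuinely compositional, every sample's counts sum
exactly to its drawn depth, and planted block correlations are known on the
basis scale — which is what SparCC estimates.

The treatment arm mixes each patient's latent profile toward a fresh healthy
draw, $z_{after} = (1-\lambda) z_{before} + \lambda z_{HC}$, before count
sampling ($\lambda = 0.7$ by default). Linked diet items follow a monotone
function of a species' observed log relative abundance plus noise calibrated
to a latent correlation of 0.4, then are discretised into ten ordinal
categories. Planted functions carry one fixed-sign status coefficient
(magnitude 0.5, noise sd 0.5) in every cohort.

One behaviour of the generator deserves emphasis because it is a feature of
compositional data, not a bug of the statistics: planting *absolute* effects
and renormalising means "null" species acquire small, cross-cohort-consistent
*relative* shifts (enriched signatures inflate the case denominator, so every
null drifts toward apparent depletion). In runs where an enriched signature
lands on a high-abundance baseline, the discovery chain admits a few percent
of nulls — correctly, in the sense that their relative abundance really is
associated with status. Real analyses face the same identifiability limit,
which is exactly why effect sizes are cross-checked on the CLR scale. Passing
tests on this generator therefore demonstrate recovery of planted structure
under compositional distortion; they do not demonstrate robustness to
sequencing-protocol batch effects, taxonomic misassignment, or
sample-collection artefacts, none of which are modelled.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero pooled SD yields an
undefined-effect marker excluded downstream (logged); fully tied Wilcoxon
groups report $p = 1$; constant vectors give undefined Spearman rho marked
`NA` and excluded from the BH family; basis variances are floored at
$10^{-12}$ before the correlation is formed and clipped to $[-1, 1]$;
rank-deficient regression designs are skipped per function (or rejected with
the aliased terms named, for PERMANOVA). Louvain ties are resolved by seeding
the community detection and relabelling modules by first-node order, making
assignments reproducible.

The test and acceptance suites run the statistical checks at sizes chosen to
finish on one CPU in minutes while keeping each check's power: the full
discovery chain at its native size (14 cohorts, 330 species, 20 replicate
runs), coverage of the random-effects CI over 200 replicates, SparCC block
recovery at 60 species and 200 samples, null-edge calibration over 741 pairs
and 20 runs, classifier schemes on reduced grids (the grid is an argument,
and out-of-bag tuning is insensitive to grid size for these planted signals),
and the treatment null calibration over 100 simulated arms. The acceptance
script reruns the whole pipeline at the native discovery size with a reduced
tuning grid and 199-permutation PERMANOVA on six pooled cohorts.

## Known limitations

Relative-abundance effect sizes inherit the compositional identifiability
limit discussed above. The treatment shift's asymmetric scoring (pre-treatment
out-of-bag, post-treatment full-model) makes its null p-value distribution
mildly non-uniform — out-of-bag probabilities are less extreme than
full-model ones, which biases the comparison *against* detecting a
probability decrease; the test's tail calibration at conventional
significance levels is verified in the acceptance suite, and the residual
bias is conservative for the directional conclusion the analysis draws. The
permutation null for network edges treats samples
as exchangeable within species and ignores residual cohort structure in the
pooled matrix. The REML fixed point can fail to converge for pathological
variance patterns, in which case the DL estimate is reported with a warning.
The diet weighting is a declared monotone stand-in, adequate for rank-based
screens only. Raw-read processing, taxonomy and function annotation, and any
download of the original cohorts are out of scope; the package starts from
annotated abundance tables.
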