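---
title: "Methods: tetrad-matched differential expression and consensus co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tetrad-matched differential expression and consensus co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and study design

`tetranet` implements an analysis pipeline for postmortem brain expression
studies built around *tetrads*: matched quartets holding one unaffected
control and one subject each with schizophrenia (SCZ), bipolar disorder
(BD), and major depressive disorder (MDD), matched for sex and closely for
age, with several brain regions (dorsolateral prefrontal cortex, hippocampus,
associative striatum) profiled from each donor. The package covers four
analysis layers — per-gene mixed-model ANCOVA, directional gene-set
enrichment, cross-disorder pathway overlap, and a signed consensus
co-expression network — plus a synthetic-data generator that emulates the
design so every layer can be exercised and benchmarked without access to
protected human data.

All expression inputs are assumed normalized and log10-scaled, complete
(no missing cells), with opaque gene identifiers. Upstream processing
(array normalization, probe annotation) is out of scope.

# Differential expression

Each gene (or qPCR/cytokine analyte) is modeled as

$$ y = X\beta + b_{\text{tetrad}} + \varepsilon,\qquad
   b \sim N(0, \tau^2),\ \varepsilon \sim N(0, \sigma^2), $$

with diagnosis as the fixed factor of interest, nuisance covariates (age,
sex, tobacco use, manner of death, postmortem interval, brain pH), and a
tetrad random intercept that absorbs the matching. Region-level analyses
drop region from the fixed effects; a pooled scope adds it back.

## The fitter

Variance components are estimated by REML. Because the model has a single
random intercept, the marginal covariance is block diagonal and an
orthonormal within-tetrad transform (scaled group-mean row plus Helmert
contrasts per tetrad) makes the generalized least-squares problem
diagonal: group-mean rows have variance $\sigma^2(1 + m\lambda)$ with
$\lambda = \tau^2/\sigma^2$ and block size $m$, contrast rows have variance
$\sigma^2$. The REML criterion is profiled over $\lambda$ with a 1-D
optimizer; each evaluation is a small weighted least-squares solve on
precomputed cross-products. This keeps genome-wide per-gene fitting at
roughly a millisecond per gene while remaining exact REML, and the tests
verify agreement with both an explicit GLS oracle (to 1e-6) and
`lme4::lmer` on the same model. The boundary $\lambda = 0$ (zero tetrad
variance) is checked explicitly; the model then degenerates to OLS, which
is allowed.

## Contrasts and selection

Disease-versus-control contrasts are least-squares-mean differences
(covariates at their means, categorical covariates at equal level
weights), tested two-tailed with *containment* degrees of freedom
$n - \mathrm{rank}(X) - T + 1$ for $T$ tetrads — a simple, conservative,
reproducible choice; Kenward–Roger/Satterthwaite approximations are
deliberate non-goals. Tukey–Kramer adjusted p-values for all pairwise
diagnosis comparisons come from the studentized range distribution with
the model-based (unequal-n safe) standard error of each difference; with
two groups this reduces exactly to the t test. With fewer than 2 residual
df the studentized range distribution is numerically undefined and the raw
p is returned with a warning.

Fold change is defined as $10^{|\hat\delta|}$ with direction carried by the
sign of the LS-mean difference, since the response is log10. DE selection
uses a strict fold cut (> 1.2) and BH-FDR < 0.05, with the FDR family being
all genes within one (region, diagnosis) contrast, because the pipeline
reports DE counts per region per diagnosis. An omnibus-first gate (FDR-score
contrasts only when the diagnosis main-effect Wald F has p < 0.05) is
available as a switch and off by default.

# Directional enrichment and pathway overlap

Over-representation of a gene set in a DE list is scored by the one-sided
hypergeometric tail (Fisher's exact test) against an explicit universe,
defaulting to all genes in the expression matrix. Gene sets come from
user-supplied GMT files; there is no built-in pathway database. Direction
is handled by scoring the up- and downregulated lists separately:

$$ \text{net} = -\log_{10} p_{\text{up}} + \log_{10} p_{\text{down}}, $$

positive when upregulated genes drive the enrichment, negative when
downregulated genes do, near zero when balanced. Whether two disorders
share more enriched pathways than chance is again a one-sided Fisher test
on the 2x2 membership table over all tested pathways. The exported
net-score matrix ranks pathways by their maximum absolute net score over
the reference diagnosis' conditions, with ties broken lexicographically
by set name so output is order-invariant.

# Signed consensus co-expression network

Per region, the adjacency is the standard signed transform
$a_{ij} = ((1 + r_{ij})/2)^{\beta}$ at $\beta = 12$; anti-correlated genes
get adjacency near zero rather than being folded onto positive
correlations. The topological overlap matrix

$$ \mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}} $$

is computed per region, single-quantile scaled (default quantile 0.95,
reference = first region in input order; both configurable), and combined
by the elementwise minimum: a pair of genes is only as similar as it is in
its least-similar region. Scale-free model fit is reported per region as
the R² of the log-log regression of binned connectivity frequencies.

Genes are optionally pre-assigned to blocks (default 4) by consensus
projective k-means — k-means on region-standardized, concatenated,
unit-norm gene profiles under the projective distance $1 - |r|$, with
sign-aligned mean centroids, several restarts, and the best-objective
assignment kept — so the TOM is materialized only within blocks, bounding
memory. Cross-block similarity is never computed; the later eigengene
merge step is what reunites split modules across blocks.

## Tree cut

Modules are found by average-linkage clustering of $1 - \mathrm{TOM}$
followed by a dynamic hybrid tree cut written for this package: maximal
branches below an absolute cut height (default 0.995 on the dissimilarity
scale) are recursively decomposed, a branch being accepted as a cluster
when its children fail validity (minimum size 50, minimum merge gap, core
scatter cap); small side branches are peeled during decomposition; a
second, hybrid stage assigns each unlabeled gene to the nearest cluster
when its mean dissimilarity to it is below that cluster's attachment
height. The deepSplit sensitivity 0–4 interpolates the core-scatter cap
over 0.64–0.96 of the working height range, with the required gap set to
three quarters of the remainder — the parameterization of the published
hybrid scheme, without claiming bit-compatibility with any existing
implementation (recovery of planted structure, not label-for-label
agreement, is the design target). The absolute cut height was chosen
because under a signed power-12 adjacency uncorrelated gene pairs sit at
dissimilarities above 0.99, so pure-noise data yields no modules at all,
while genuinely co-expressed blocks merge far below the cut.

## Refinement, reassignment, merging

Module eigengenes (MEs) are the first principal component of the module's
region-standardized expression, unit-norm, oriented so the mean membership
correlation (kME) of the module's own genes is positive. Refinement
applies, in order: removal of genes with own-module kME < 0.3; disbanding
of modules with fewer than 17 genes at kME > 0.5 ("fewer than 17" is read
strictly); recomputation; then a single reassignment pass in which a gene
moves to another module when its correlation p-value (Fisher z, the same
asymptotic p used for ME–trait tests) to that ME is smaller than its
own-module p by a factor of 1e-4. Finally MEs are clustered by
$1 - \mathrm{cor}$, the dendrogram cut at 0.15 (i.e. eigengene correlation
0.85, on signed r), all modules on a branch merged, and the process
iterated to a fixed point; termination is guaranteed because the module
count strictly decreases. Labels are canonicalized by decreasing size with
ties broken by the lexicographically smallest member gene, so labels are
invariant to gene input order.

ME–trait association uses Pearson correlation with the Fisher-z asymptotic
p-value ($z = \operatorname{atanh}(r)\sqrt{n-3}$, two-tailed normal) and
BH-FDR across the full module x trait x region grid. Diagnosis traits are
one-vs-rest indicators over all subjects by default (a one-vs-control
coding that drops the other disorders is available). Per-region statistics
restrict the concatenated-sample eigengene to that region's samples —
correlation is scale-free, so the restriction of the global ME is used
directly. DE enrichment of modules reuses the same Fisher machinery as the
pathway layer.

# qPCR validation statistics

Reference genes are chosen by a model-based stability value in the
NormFinder spirit: replicate wells (quadruplicate at most) are collapsed
to mean quantities, log10-transformed, and centered per sample to remove
loading artifacts; a two-way gene x group decomposition yields per-gene
intergroup bias (the interaction term), shrunken by a moment estimator of
the between-gene bias variance, and intragroup variance; the stability
value is the mean over groups of |shrunken bias| + sqrt(variance /
group size), lower being more stable, with ties broken by lower intragroup
variance. The published method's exact constants are not reproduced; the
decomposition and the bias/variance trade-off are. A two-step funnel
(default 6 then 3) mirrors the usual candidate screen. Normalized
quantities divide the gene of interest by the geometric mean of the three
reference genes; analysis of normalized quantities (or cytokine
concentrations) log10-transforms and delegates verbatim to the ANCOVA
layer.

# The synthetic-data generator

`simulate_study()` emulates the matched design: per gene, subject and
region,

$$ y = \text{baseline}_g + b_{g,t,r} + \text{diagnosis effect}
     + \text{covariate effects} + \textstyle\sum_m \ell_{g,m} s_{s,r,m}
     + N(0, \sigma), $$

with a per-gene tetrad random intercept $b$ (sd 0.05), rank-one module
factors (loading $\ell$ x per-subject score $s$), and residual sd 0.1 on
the log10 scale. Age and sex are matched within tetrad (tetrad-level base
values with small jitter); tobacco, manner of death, PMI and pH vary per
subject; sparse nuisance covariate effects (5% of genes per covariate,
small coefficients) give the ANCOVA something real to absorb without
letting covariates dominate the correlation structure. Module inter-gene
correlation is controlled by the loading-to-noise ratio
($\ell = \sigma\sqrt{\rho/(1-\rho)}$), the simplest generative model with
a well-defined first principal component. A trait-associated module shifts
its factor score for the associated diagnosis, which both correlates the
eigengene with the diagnosis indicator and makes the members genuinely
differentially expressed; these module-induced effects are bookkept in the
returned truth alongside the per-gene plan.

Default conditions: 19 tetrads, 2000 genes, three regions. The planted DE
fractions follow the graded burden of the motivating design — SCZ 9%/3%/2%
of genes in hippocampus/striatum/prefrontal cortex, with BD (2%/1%/0.8%)
and MDD (0.5%/0.3%/0.2%) much smaller; the study this emulates reports
only the SCZ regional percentages, so the BD/MDD splits are package
choices respecting the qualitative ordering. Mean |log10 effects| are 0.20
(SCZ) and 0.18 (BD/MDD), i.e. about 1.5–1.6-fold, drawn as
N(mean, mean/5) floored at mean/2 so planted effects sit clearly above
the 1.2-fold selection cut; five planted modules have sizes
122/250/150/80/60 and inter-gene correlations 0.5–0.6, with the 122-gene
module SCZ-associated (score shift 2.5 SD, upregulated, all regions) as an
inflammation-like fixture. These defaults are deliberately at the
clearly-recoverable end: within-tetrad variance components are not
reported by any study this design emulates, and the generator's job is
clean desk-scale recovery benchmarking, not realism. Consequently, passing
recovery tests demonstrates correctness of the machinery under the stated
generative model — not performance on real microarray data, which has
probe-level noise, batch structure, RNA-degradation artifacts and
non-Gaussian tails that the generator intentionally omits.

Randomness is staged: the subject-level draw, the gene-level draw, and
each region's noise use separate streams derived from one master seed, so
changing the gene count does not reshuffle the covariates. Fixture
emission (`emit_fixture()`) writes the TSV/GMT files every other layer
consumes, including the planted modules as gene sets plus random decoy
sets, and is byte-identical across re-runs.

# Numerical choices and degenerate inputs

* Expression values are written with 17 significant digits so write/read
  round trips are bitwise exact.
* A constant response yields zero variance components; contrast t
  statistics treat |estimate| below 1e-10 with zero SE as exactly zero
  (p = 1) and anything larger as certain (p = 0).
* `phyper`/`fisher.test` supply all hypergeometric tails; tests verify
  them against exhaustive log-binomial enumeration for every 2x2 table
  with margins up to 60.
* Zero-variance genes are rejected by name before any correlation.
* TOM and consensus values are clipped to [0, 1]; the consensus is never
  above any scaled regional TOM.
* Tree-cut labels use 0 for unassigned genes throughout.

# Problem sizes

The bundled tests and the acceptance script run the full pipeline at the
default study conditions (2000 genes, 19 tetrads, 3 regions) and repeat
the recovery experiments over ten seeds; these sizes keep a complete run
on a single desk-scale core in a few minutes while leaving the planted
structure unambiguous.

# Known limitations

* The dynamic hybrid cut is this package's own implementation of the
  published scheme's ideas; branch-by-branch agreement with other
  implementations is not a goal, and its absolute cut height (0.995) is
  tuned to the signed power-12 adjacency scale — other powers or unsigned
  networks may need a different `cut_height`.
* Containment df is conservative; small designs lose a little power
  relative to Satterthwaite-type approximations.
* The stability model reproduces the NormFinder decomposition, not its
  exact published constants.
* One-vs-rest trait coding is a choice; the alternative coding is exposed
  because published analyses are often ambiguous on this point.
* Missing values are rejected rather than imputed.
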