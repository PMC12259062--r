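---
title: "Modeling surface-protein abundance through intracellular transport: trios, mediation, and sparse selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling surface-protein abundance through intracellular transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(surfmed)
```

## The problem

CITE-seq measures, in the same cell, the transcriptome and the abundance of a
panel of surface proteins read out through antibody-derived tags (ADTs). The
two measurements routinely disagree: a protein can be strongly shifted on the
cell surface while its coding gene's mRNA is flat. One mechanistic candidate
for that gap is intracellular transport (ICT) — the ER-to-Golgi secretory
route, vesicle trafficking, and endocytic recycling that place a protein on
the membrane and remove it again. ICT is itself transcriptionally regulated,
so the transcription of ICT genes carries a signal about how much transport
capacity a cell is devoting to its surface proteome.

`surfmed` quantifies that signal in four steps, each a model with an explicit
estimand, and ships a simulator so that every step is testable against
planted ground truth.

## The unit of analysis: trios

A *trio* is (surface protein `m`, one of its coding genes `g`, ICT gene
`t`). Multi-subunit proteins contribute one trio family per subunit gene:
CD3 maps to CD3D/CD3G/CD3E, HLA-DR to HLA-DRA/-DRB1/-DRB5, and CD16 to six
FCGR genes, so a 30-protein panel with those three multi-subunit entries
expands to 39 (protein, coding gene) pairs. The catalog is the cartesian
product of pairs with the measured ICT genes, minus trios where the ICT gene
*is* the coding gene. That self-exclusion is a package choice, exposed as
`exclude_self`: a handful of immune coding genes (CD14, CD74, ...) are
themselves annotated to transport processes, and letting a gene act as its
own transport regulator would make the trio model circular. The shipped
`ict_genes_example.tsv` is a small illustrative list of well-known
trafficking genes for examples and tests; a real analysis supplies its own
genome-wide curation as input.

## Step I — the trio mixed-effects model

For cells of one phenotype group, with `E` the normalized ADT abundance and
`X` normalized transcription,

$$E_{m,c} = \eta_0 + \eta_1 X_{g,c} + \eta_2 X_{t,c} + \textstyle\sum \zeta V_c
  + u_{s(c)} + \varepsilon_c,\qquad u_s \sim N(0, \sigma_u^2)$$

The sample random intercept `u_s` is essential: cells from one donor are not
independent, and pooling thousands of them without it would wildly overstate
significance. The coefficient of interest is $\eta_2$ — the association of
ICT-gene transcription with surface abundance *after* accounting for the
protein's own transcription. Estimation is by REML through `lme4`; the
$\eta_2$ p-value is a Wald z-test by default (a Satterthwaite option via
`lmerTest` exists for small-sample work, where the z approximation is
anti-conservative). With hundreds of cells per group the two agree to the
third decimal. Trios significant at Benjamini–Hochberg FDR < 0.05 within a
phenotype group are *putative transport trios* (PTTs). Fits that fail or do
not converge stay in the output table but are excluded from the BH family —
an invalid p-value inside the family would distort every other trio's FDR.
Singular fits ($\hat\sigma_u^2 = 0$) are *not* failures; they are the
correct answer when samples genuinely share a mean, and the fixed effects
then reproduce ordinary least squares, which is one of the test suite's
oracles.

$R^2$ is reported as the squared Pearson correlation between fitted
(fixed + random) and observed values — a conditional flavor, chosen because
the full-versus-reduced comparison (`compare_reduced()`) aggregates it
across trios and only differences matter there. That comparison retains, per
(protein, coding gene) pair, the maximum $\eta_1$, the minimum $\eta_1$
p-value and the mean $R^2$ across the pair's trios, against a reduced model
without the ICT term.

```{r ptt-demo}
sim <- make_fixture("one-strong-trio")   # one trio planted with eta2 = 1
ds <- sim$dataset
catalog <- build_trios(data.frame(m = "P1", g = "G1"),
                       sim$truth$ict_genes, colnames(ds$rna))
ptt <- scan_trios(ds, catalog, group = "healthy")
ptt
```

## Step II — single-exposure mediation

For each PTT, does the surface protein *transmit* the ICT gene's effect to
the phenotype? With `x` the ICT transcription, `m` the protein abundance,
and `d` the phenotype coded 0/1 for a chosen contrast:

$$m = \varphi_0 + \alpha x + \varsigma, \qquad
  d = \omega_0 + \beta m + \delta x + \xi$$

The indirect effect is $\alpha\beta$, the direct effect $\delta$, and their
sum is *exactly* the slope of `d` on `x` alone — the decomposition identity
of linear mediation, which holds to machine precision and is asserted in the
tests. This is also why the outcome equation stays linear for a binary
phenotype (a linear-probability reading): a logistic outcome would break the
identity. The phenotype enters at the cell level although it is assigned at
the sample level; the package deliberately leaves random effects out of the
mediation equations (they were already used to screen trios), which is a
known limitation — mediation p-values here are anti-conservative to the
extent that sample-level variation leaks into the contrast.

Inference on $\alpha\beta$ uses the Sobel delta-method standard error by
default, $\sqrt{\alpha^2\,\mathrm{se}(\beta)^2 + \beta^2\,\mathrm{se}(\alpha)^2}$,
with a seeded percentile bootstrap as an option; on well-powered fits the
two agree in their rejection decisions, and the bootstrap is preferable near
the null where the product distribution is non-normal. Classification at
level 0.05 (nominal, matching the screening character of this step; a BH
variant is one `p.adjust()` away on the scan table): significant indirect
only → *full* mediation; both → *partial*; direct only → *none*; neither →
not disease-associated. Genes in the first three classes are daICT
(disease-associated ICT) genes.

```{r mediate-demo}
x <- ds$rna[, "ICT1"]; m <- ds$adt[, "P1"]
d <- as.numeric(ds$meta$phenotype == "severe")
mediate(x, m, d)
```

## Step III — many exposures, one mediator, L1 selection

ICT genes are correlated; testing them one at a time overcounts. The
multi-exposure model takes all ICT genes with strong trio effects
(`|eta2| > 0.1`, strict) as joint exposures and minimizes

$$\tfrac{1}{2n}\lVert m - \varphi_0 - X\alpha\rVert^2
 + \tfrac{1}{2n}\lVert d - \omega_0 - X\delta - \beta m\rVert^2
 + \lambda\, w(1,r)\,\big(\textstyle\sum_t |\alpha_t| + \sum_t |\delta_t|\big)$$

with $w(1,r) = r^{1/4}$ balancing the penalty against the number of
exposures. $\beta$ and the intercepts are never penalized — the
mediator-to-phenotype link is always retained. Because the first residual
term involves only $\alpha$ and the second only $(\delta, \beta)$, the joint
problem decouples into two penalized least-squares problems; each is solved
by cyclic coordinate descent with soft-thresholding, run to a stationary
point (largest coefficient update below 1e-7, cap 10,000 sweeps). The
solver is validated three ways: against the closed-form soft-threshold
solution on an orthonormalized single exposure, against `glmnet` on the
mediator equation, and against unpenalized least squares at $\lambda = 0$.
Exposures and the mediator are z-scored before fitting so one $\lambda$
grid is scale-free; coefficients are reported on that standardized scale.

$\lambda$ is chosen on a grid (default 11 evenly spaced values on
[0.005, 0.03], warm-started ascending) by minimizing
$\mathrm{BIC} = n\log(\mathrm{RSS}_m/n) + n\log(\mathrm{RSS}_d/n)
+ k\log n$, with $k$ the nonzero penalized count plus three (the standard
lasso degrees-of-freedom result); BIC ties go to the smaller $\lambda$,
keeping the less sparse candidate for the Step II/III comparison.
Classification then reads the sparsity pattern — exact zeros replace
p-values, which a penalized fit does not honestly provide: nonzero
$\alpha_t\beta$ with zero $\delta_t$ is full mediation, both nonzero is
partial, only $\delta_t$ nonzero is null, both zero drops the gene. An
optional `refit` pass debiases the surviving coefficients by unpenalized
least squares on the selected support; it is off by default so that
reported coefficients correspond to the selected model itself.
`compare_modules()` cross-tabulates the two classifications, the dropped
genes landing in an `NA` column, with mean |indirect| and |direct| effect
sizes for retained versus dropped genes.

```{r medlasso-demo}
sm <- make_fixture("sparse-mediation-20")  # 3 of 20 exposures active
path <- medlasso_path(sm$dataset$rna[, sm$truth$ict_genes],
                      sm$dataset$adt[, "P1"], sm$dataset$meta$D_latent)
path
path$fit$support$alpha
```

## Step IV — the regulatory network

The classification table becomes a signed directed graph: `t -> m` for full
mediation, `t -> m` and `t -> D` for partial, `t -> D` for null; the
protein–phenotype edge `m -> D` is always present; the coding gene and its
`g -> m` edge enter only when transcription earned it (trio-model
significance or differential expression). Edge weights are the standardized
coefficients that defined each edge ($\alpha_t$, $\delta_t$, $\beta$,
$\eta_1$) and signs are carried as colors (red positive, blue negative).
The rules admit no cycles, so every network is a DAG. Export formats:
GraphML and TSV edge list (lossless round trip), DOT (write-only).

## The simulator and what passing tests mean

`simulate_citeseq()` draws transcription as i.i.d. standard normals, adds
per-sample Gaussian intercepts, and builds protein abundance from the trio
equation — exactly the generative assumptions of the models, which is the
point: it isolates the estimators from questions of data realism. Two
outcome modes exist because they answer different questions.
`binary_sample` assigns phenotype at the sample level, like a real
multi-donor study, and realizes effects as group shifts; it is the right
mode for testing detection (type-I error, PTT recall). `continuous_latent`
emits a per-cell Gaussian outcome from the mediation equations; it is the
only mode in which planted $(\alpha, \delta, \beta)$ are exactly the
estimands, so recovery tests use it. An optional negative-binomial emission
(dispersion 0.5) maps latent values through `exp(a + b·latent)` into counts
to exercise QC and normalization; it models overdispersion but not dropout,
ambient contamination, or library-size gradients, so passing tests certify
the estimators and the pipeline plumbing, not robustness to every artifact
of real droplet data.

Default study conditions follow the scale of a small clinical CITE-seq
cohort: 12 donors across three phenotype groups (5/3/4), around 100 cells
per donor per analysis subset, sample-intercept sd 0.5 against residual sd
1. The registered fixtures pin the test-suite scenarios: `tiny-null` (4
donors, nothing planted), `one-strong-trio` (one $\eta_2 = 1$ trio among
nine nulls, 600 cells in the analyzed group), and `sparse-mediation-20`
(20 exposures, 3 active at $\alpha = \delta = 0.4$, $\beta = 0.5$,
n = 2000). Simulation sizes throughout the suite (500 replicates for test
size, 200 for coverage, 50 seeds for support recovery) were sized to keep
Monte-Carlo error well inside the asserted bands.

## Numerical and preprocessing choices

* **QC order is fixed**: cell filter (≥ 100 detected genes), then gene
  filter (detected in ≥ 5 cells), then mitochondrial filter (≤ 5%,
  prefix-matched, default `MT-`). The order matters — the gene filter sees
  only surviving cells — and is regression-tested on a fixture where the
  orders disagree. All thresholds are strict on the removal side.
* **RNA normalization**: library-size scaling to 10,000, `log1p`, then
  per-gene z-transform across the whole dataset. Z-scoring happens before
  any per-phenotype subsetting (a `group_by` option inverts that), so
  coefficients are comparable across groups at the cost of letting group
  composition into the gene scale.
* **ADT normalization**: centered log-ratio within each cell (ADT counts
  are compositional per cell; a per-protein margin is provided for narrow
  panels), pseudocount +1, then per-protein z-transform. The CLR layer
  rows sum to zero; the z layer has exact unit columns — both are asserted
  at 1e-10.
* **Rank-sum tests** use the exact null for small untied groups and the
  tie-corrected normal approximation otherwise; all-tied comparisons are
  reported as p = 1 rather than NaN.
* **Degenerate inputs** fail loudly and early: constant predictors,
  single-sample groups, empty contrast groups, zero-count cells, and
  unannotated cells are errors, not silent drops; per-trio failures in a
  scan are logged rows, not exceptions.

## Known limitations

Sample-level dependence is modeled in Step I only; Steps II–III treat cells
as independent. The linear-probability outcome can predict outside [0, 1]
and its error variance is heteroscedastic; it is kept for the exactness of
the decomposition, with a logistic option deliberately excluded from the
default path. The lasso excludes weak but real effects by design — the
Step II/III comparison is the recommended recovery route for those. And the
simulator's Gaussian world cannot certify behavior under real droplet
artifacts; it certifies the mathematics.
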